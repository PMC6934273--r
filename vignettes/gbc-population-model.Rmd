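---
title: "Methods: adaptive coincidence counting and population screening of globular bushy cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive coincidence counting and population screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model and its assumptions

Globular bushy cells (GBCs) integrate many converging auditory-nerve (AN)
synapses and improve the temporal precision of the spike trains they relay.
`gbcpop` models a GBC as an *adaptive coincidence counter*: every input
spike contributes a rectangular count of duration `wE` (the coincidence
window) and amplitude `aE` relative to a static threshold fixed at 1. The
summed count `v(t)` triggers an output spike whenever it reaches the total
threshold `1 + thetaD(t)`, after which the model is absolutely refractory
for `tR` ms. The dynamic threshold follows

$$T_A \frac{d\theta_D}{dt} = -\theta_D(t) + S_A\, v(t),$$

relaxing toward `sA * v` with time constant `tA`. High `sA` and short `tA`
make the threshold track the recent input level closely, so only inputs
that arrive more synchronously than the recent past can fire the cell.
This is the entire mechanism: there are no membrane conductances, no
synaptic depression, no inhibition, and no axonal or synaptic delays. The
output variability is inherited entirely from the stochastic inputs — the
neuron itself is deterministic.

Because the inputs are rectangles on a fixed grid (`dt` = 0.01 ms),
`v(t)` is constant within each step and the threshold equation has an
exact per-step solution, implemented in `updateThreshold()` and inside the
compiled simulation kernel:

$$\theta_D(t+\Delta t) = e^{-\Delta t/T_A}\,\theta_D(t) +
  \left(1 - e^{-\Delta t/T_A}\right) S_A\, v(t).$$

No ODE discretization error is incurred; the test suite checks the
iterated update against closed-form relaxation (to 1e-12 relative) and
against an independent adaptive ODE solver restarted at every jump of
`v(t)` (to 1e-6 relative). A plain fixed-step Euler oracle at `dt/1000`
is *not* accurate enough for the latter bound (its one-step relative error
is about 2e-5 here), which is why the suite uses an adaptive solver as the
reference.

## Per-step order of operations

Within one grid step the kernel (1) updates `v` from the input events,
(2) emits a spike if the model is not refractory and `v >= 1 + thetaD`,
and (3) advances `thetaD` using this step's `v`. The threshold is compared
*before* it absorbs the current step's input; the dynamic threshold is a
function of the input history only — it is never reset by output spikes
and keeps integrating during refractoriness. Other conventions:

* a spike at time `s` contributes to `v(t)` for `t` in `[s, s + wE)`
  (half-open, no double counting at the trailing edge);
* `wE` and `tR` are quantized to the grid by round-half-up, the window to
  at least one step;
* simultaneous inputs sum linearly; "reaches or exceeds" is an exact
  floating `>=` (safe because `v` is `aE` times an integer count);
* the model starts with `thetaD = 0` and non-refractory, so a spike may
  occur at the first step.

# The model parameters

| parameter | meaning | unit | default | grid range |
|---|---|---|---|---|
| `mE` | number of excitatory AN inputs | — | 20 | 9–36 (7 values) |
| `wE` | coincidence window | ms | 0.32 | 0.08–0.80 (10) |
| `aE` | input amplitude / static threshold | — | 0.40 | 0.24–0.56 (9) |
| `tR` | absolute refractory period | ms | 1.20 | 0.70–1.50 (9) |
| `tA` | adaptation time constant | ms | 0.25 | 0.05–0.50 (10) |
| `sA` | adaptation strength | — | 0.80 | 0.40–1.30 (10) |

The defaults are the reference PL_N instance used in all single-instance
examples; the value lists define the full screening grid of 567,000
instances (`buildGrid()`). `deskGrid()` is the package's desk-scale
profile — the two extremes plus the default value in each dimension
(729 instances) — chosen so the reference instance always lies on the
reduced grid.

# The auditory-nerve surrogate

The screening workflow needs AN spike trains with realistic statistics.
`generateANTrains()` is a phenomenological surrogate, not a cochlear
model: it emulates, at the descriptor level, what a full auditory
periphery model delivers to a GBC from high-spontaneous-rate fibers.

* **Rates.** Spontaneous rate 70 spikes/s; driven rate follows a sigmoid
  rate-level function between 0 and 40 dB SPL saturating at 250 spikes/s,
  multiplied by exponential onset adaptation (peak ratio 3, time constant
  5 ms). The stimulus amplitude ramp (3.9 ms for tone bursts) is converted
  to an instantaneous level *before* the sigmoid, which reproduces the
  sharp AN onset at high levels despite the slow pressure ramp.
* **Phase-locking.** Spikes drawn from the rate envelope are snapped to
  the preferred stimulus phase with wrapped-Gaussian jitter. The jitter SD
  comes from the closed-form Fourier coefficient of the jitter density,
  `VS = exp(-sigma^2/2)`, targeting a frequency-dependent ceiling
  `vsMax / (1 + (f/corner)^slope)` (defaults 0.85, 1100 Hz, 2.5 — about
  0.8 at 350 Hz, near zero at 7 kHz). For SAM tones the snap acts at the
  modulation frequency with the target scaled by modulation depth, so zero
  depth degenerates exactly to the tone case.
* **Refractoriness.** Absolute dead time 0.45 ms plus exponential relative
  recovery (0.5125 ms) applied by sequential thinning; the driving rate is
  pre-compensated by numerically inverting the renewal-theory relation
  between driving and realized rate, so the realized rate matches the
  envelope.
* **Tuning.** A V-shaped attenuation filter (40 dB/octave below CF,
  120 dB/octave above) feeds the rate-level function; below-CF attenuation
  is capped at 40 dB, giving high-CF fibers the low-frequency "tail"
  response that intense low tones exploit.
* **Seeding.** A master seed spawns per-fiber, per-trial child seeds
  through an injective Lehmer-generator hash (`childSeed()`), so the same
  seed reproduces the whole data set bit for bit and any single
  fiber/trial can be regenerated in isolation.

What the surrogate does **not** emulate: cochlear filtering and
suppression, hair-cell transduction, power-law adaptation,
fractional-Gaussian-noise spontaneous statistics, and spontaneous-rate
classes other than high-SR. Tests passing with the surrogate therefore
show that the GBC stage behaves correctly given inputs with the assumed
first-order statistics; they do not validate the periphery itself, and
population counts obtained with the surrogate are not comparable to
counts obtained with a full periphery model. Externally computed AN spike
trains can be substituted through `loadANTrains()`.

# Output measures and classification

All sustained measures use the 10–25 ms window of the 25 ms tone response
(for SAM, everything after the first 10 ms). Vector strength is computed
on spikes pooled across trials — the resultant of per-spike phases — and
interspike intervals never straddle trial boundaries. `cvPrime()` uses
the population (divide-by-N) standard deviation, which matters only for
tiny fixtures; its dead-time correction is 0.5 ms. Undefined measures
(no spikes, no ISIs, mean ISI at or below the dead-time correction)
propagate as `NA`, never as silent zeros.

PSTHs use 0.1 ms bins and five-point triangular smoothing with kernel
(1,2,3,2,1)/9, which preserves the total count for interior spikes. The
feature extractor takes the first peak as the global maximum in the 0–5 ms
onset region; notches are contiguous spans below 90% of the sustained
rate (the first such span is "the" notch; its width is the span length);
the second peak is the maximum between the first and second spans, or — if
there is no second span — the pre-sustained maximum, reported only when it
overshoots the sustained rate by more than 5% so that a monotone recovery
is not mistaken for a peak. When the rate grazes the 90% line several
times, the first contiguous sub-threshold span is used.

Classification applies: spontaneous rate < 30 spikes/s; driven rate
>= 150 spikes/s (PL_N) or in [50, 150) (On_L) — the half-open split makes
the categories disjoint at the boundary; CV' in the closed interval
[0.65, 0.95]; VS > 0.9 and EI > 0.9 at 350 Hz. Instances passing the rate
criteria but failing P3 (second peak at least half the first) are labelled
choppers; failing P2 or P4 (notch-width bounds), dippers. The visual
inspection step used with physiological data is replaced by these
deterministic rules alone, so ambiguous shapes are classified strictly by
P1–P4. A separate no-notch ("PL") category is not implemented.

# Population screening

`runSelection()` shares AN inputs across all instances with the same
`mE` — instance differences are purely postsynaptic, and caching is what
makes the screen tractable; a test asserts that cached and uncached
evaluations agree exactly. Screening is deterministic given the master
seed, and chunked checkpointing lets an interrupted screen resume.

Problem sizes are a package choice: the desk profile uses 100 trials per
tone and 10 s of continuous silence per instance, the full protocol 1000
trials and 100 s. Spontaneous rate uses one continuous silence stretch
rather than many short trials so that no onset transients contaminate it.

`dimensionalStack()` nests the six dimensions as three (row, column) pairs
— outer, middle, inner — with the reference layout (mE, sA), (aE, tR),
(wE, tA); on the full grid this gives a 630 × 900 image with each instance
in exactly one cell.

For frequency response areas, thresholds are interpolated linearly in dB
at the level where the rate crosses 10 spikes/s above the spontaneous
rate, and Q10 interpolates the threshold curve linearly in log-frequency
10 dB above the minimum. Rate-level functions are forced monotone
(cumulative maximum) before interpolation: the model's rate-level function
is monotone, and enforcing it keeps sampling noise from producing spurious
crossings. Longer tone bursts (e.g. 60 ms) are used for FRA runs to
stretch the sustained window and cut the rate-estimate variance.

# Parameter-space analyses

* **Connectivity.** Order-*n* neighbors differ by one grid step in at most
  *n* dimensions (an interior point has 12 one-dimensional neighbors).
  Components are computed over the accepted set only; the count is weakly
  decreasing in *n*.
* **Convexity.** Random parent pairs from the accepted set are
  interpolated at fractions 1/4, 1/2, 3/4 (three evenly spaced interior
  points); `mE` is rounded to the nearest integer because fiber counts are
  physical integers, the other parameters stay continuous, and children
  are *not* snapped to the grid — the evaluator runs the full battery on
  off-grid parameter vectors.
* **Correlations.** Pearson coefficients on raw parameter values (r is
  scale-invariant, so z-scoring would not change it), flagged at |r| > 0.2
  with p < 1e-9.
* **Regressions.** Inputs are z-scored; outputs transformed as log(SR),
  log(DR), log(1-VS), log(1-EI) with CV' untransformed. Natural logs —
  the base does not affect R². Rows outside a transform's domain (zero
  rates, VS or EI equal to 1) are excluded with the count reported. The
  linear basis has 6 terms, quadratic 27 (adding 6 squares and 15
  products), cubic 83. Fits run on centered moment matrices via the sweep
  operator; a rank-deficient design raises an error rather than being
  silently regularized. Note that cubic terms are structurally collinear
  with linear ones on a grid with only three levels per dimension, so
  cubic fits require the richer full grid.
* **Variance decomposition.** Terms are added one at a time and the gain
  in R² is averaged over orderings: all 720 orderings in linear mode
  (making the gains exactly the Shapley values of R², and their sum the
  total R²), and randomly sampled orderings of the 21 quadratic terms in
  quadratic mode, each ordering starting from the complete linear fit so
  no quadratic term ever precedes its linear components. The sampling
  default (40,000 orderings) is configurable down for interactive use.

# Known limitations

The surrogate's onset-peak magnitude and notch-recovery shape are
qualitative emulations, so PSTH-shape boundaries (and hence accepted
counts) shift with the periphery used; only the combinatorial and
analytic results are periphery-independent. The model omits inhibition,
so no sideband suppression can appear in FRAs. Off-CF behavior is reduced
to a fixed two-slope filter with a tail cap. Measures at the edges of
their domains (VS or EI of exactly 1) are excluded from log-scale fits
rather than winsorized.
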