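# Phenomenological auditory-nerve surrogate. It emulates, at the descriptor
# level, the input statistics a full auditory-periphery model would provide
# to the GBC stage: spontaneous rate, saturating onset-adapted driven rate,
# frequency-dependent phase locking, refractoriness, and a V-shaped tuning
# filter with a capped low-frequency tail.

# Rate-level sigmoid: ~0 at the threshold level, ~1 at saturation. The scale
# is an eighth of the dynamic range so the two endpoints sit at the 2% and
# 98% points.
rateLevelSigmoid <- function(level, p) {
  mid <- (p@rateThresholdLevel + p@rateSaturationLevel) / 2
  sc <- (p@rateSaturationLevel - p@rateThresholdLevel) / 8
  1 / (1 + exp(-(level - mid) / sc))
}

# Tuning-filter attenuation (dB) of a stimulus frequency seen by a fiber at
# `cf`. Above CF the slope is steep; below CF the attenuation is capped at
# tailThresholdShift, producing the low-frequency tail of high-CF fibers.
tuningAttenuation <- function(frequency, cf, p) {
  if (cf <= 0 || frequency <= 0) return(0)
  oct <- log2(frequency / cf)
  if (oct >= 0) p@tuneSlopeHi * oct
  else min(p@tuneSlopeLo * (-oct), p@tailThresholdShift)
}

#' Target vector strength of surrogate AN fibers
#'
#' Frequency-dependent ceiling of AN phase-locking:
#' \code{vsMax / (1 + (f/vsCornerFreq)^vsSlope)}, a monotone decay above the
#' corner frequency (approximately 0.8 at 350 Hz and near zero by 7 kHz with
#' the defaults).
#'
#' @param frequency reference frequency (Hz), vectorized.
#' @param p an \code{ANSurrogateParameters} object.
#' @return target VS values in [0, 1).
#' @export
anTargetVS <- function(frequency, p = ANSurrogateParameters()) {
  p@vsMax / (1 + (frequency / p@vsCornerFreq)^p@vsSlope)
}

#' Instantaneous firing-rate envelope of a surrogate AN fiber
#'
#' Builds the deterministic rate profile (spikes/s) on the simulation grid.
#' Silence gives the flat spontaneous rate. For tones the stimulus amplitude
#' ramp is converted to an instantaneous level and passed through the
#' sigmoid rate-level function, so at high levels the effective onset is
#' sharp even with a 3.9 ms amplitude ramp (as in real AN responses); the
#' driven term is additionally multiplied by exponential onset adaptation
#' decaying from \code{onsetPeakRatio} to 1. For SAM tones the driven term
#' is further modulated by \code{1 + modDepth * sin(2 pi fm t)} and
#' rectified.
#'
#' @param stim a \code{StimulusDescriptor}.
#' @param p an \code{ANSurrogateParameters}.
#' @param dt grid step (ms).
#' @return numeric vector of rates (spikes/s), one per grid step.
#' @examples
#' r <- rateEnvelope(toneStimulus(350, 70), dt = 0.1)
#' range(r)
#' @export
rateEnvelope <- function(stim, p = ANSurrogateParameters(), dt = 0.01) {
  validObject(stim); validObject(p)
  n <- stepsRoundHalfUp(stim@duration, dt)
  tms <- (seq_len(n) - 1) * dt
  if (stim@kind == "silence") return(rep(p@spontRate, n))
  amp <- rep(1, n)
  if (stim@riseFall > 0) {
    amp <- pmin(1, pmin(tms, stim@duration - tms) / stim@riseFall)
    amp <- pmax(amp, 0)
  }
  levelT <- stim@level + 20 * log10(pmax(amp, 1e-6)) -
    tuningAttenuation(stim@frequency, stim@cf, p)
  driven <- (p@maxDrivenRate - p@spontRate) * rateLevelSigmoid(levelT, p)
  onset <- 1 + (p@onsetPeakRatio - 1) * exp(-tms / p@onsetTau)
  driven <- driven * onset
  if (stim@kind == "sam" && stim@modDepth > 0) {
    mod <- 1 + stim@modDepth * sin(2 * pi * stim@modFrequency * tms / 1000)
    driven <- driven * pmax(mod, 0)
  }
  pmax(p@spontRate + driven, 0)
}

# ---- refractory rate compensation -------------------------------------
# Thinning by the dead time lowers the realized rate below the driving
# rate. For a homogeneous driving rate lambda (spikes/s) with absolute dead
# time d and exponential relative recovery tau (ms), the accepted process is
# a renewal process with mean interval
#   T(lambda) = d + int_0^inf exp(-lambda [u - tau (1 - e^{-u/tau})]) du .
# We invert 1/T(lambda) = target numerically and cache the inversion as a
# monotone spline per (d, tau) pair.

meanThinnedITI <- function(lambdaMs, d, tau) {
  # lambdaMs in spikes/ms; returns mean accepted ITI in ms
  f <- function(u) exp(-lambdaMs * (u - tau * (1 - exp(-u / tau))))
  if (tau <= 0) return(d + 1 / lambdaMs)
  d + stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

anInflationFun <- local({
  cache <- new.env(parent = emptyenv())
  function(p, maxRate = 4000) {
    key <- sprintf("%.6g_%.6g_%g", p@absRefractory, p@relRefractory, maxRate)
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- p@absRefractory; tau <- p@relRefractory
    if (d <= 0 && tau <= 0) {
      f <- identity
    } else {
      lam <- exp(seq(log(1e-3), log(maxRate * 3 / 1000), length.out = 60))
      realized <- vapply(lam, function(l) 1 / meanThinnedITI(l, d, tau),
                         numeric(1)) * 1000   # spikes/s realized
      sf <- stats::splinefun(realized, lam * 1000, method = "hyman")
      f <- function(r) ifelse(r <= 0, 0, sf(pmin(r, max(realized) * 0.999)))
    }
    cache[[key]] <- f
    f
  }
})

# ---- spike generation --------------------------------------------------

# Draw one fiber-trial from an inhomogeneous Poisson process with the given
# driving-rate envelope (spikes/s on the dt grid), then optionally snap
# spikes to the preferred phase of `lockFreq` with wrapped-Gaussian jitter
# targeting `targetVS`, and finally apply dead-time thinning.
drawFiberTrial <- function(env, dt, duration, lockFreq, targetVS, p) {
  cum <- cumsum(env) * dt / 1000       # expected counts
  total <- cum[length(cum)]
  n <- stats::rpois(1, total)
  if (n == 0) return(numeric(0))
  u <- sort(stats::runif(n, 0, total))
  idx <- findInterval(u, cum) + 1
  tt <- (idx - 1 + stats::runif(n)) * dt
  if (!is.null(lockFreq) && lockFreq > 0 && targetVS > 0.01) {
    period <- 1000 / lockFreq                       # ms
    sigma <- sqrt(-2 * log(targetVS)) / (2 * pi) * period
    tt <- round(tt / period) * period + stats::rnorm(n, 0, sigma)
    tt <- tt[tt >= 0 & tt < duration]
  }
  tt <- sort(tt)
  uu <- stats::runif(length(tt))
  .anThinRefractory(tt, p@absRefractory, p@relRefractory, uu)
}

#' Generate surrogate auditory-nerve spike trains
#'
#' Draws statistically independent fibers from an inhomogeneous point
#' process with the [rateEnvelope()] profile. Phase-locking is realized by
#' snapping spikes to the preferred stimulus phase with wrapped-Gaussian
#' jitter whose width is chosen from the closed-form Fourier coefficient
#' \eqn{VS = e^{-\sigma^2/2}} of the jitter density, targeting
#' [anTargetVS()] at the tone frequency (or, for SAM, at the modulation
#' frequency with the target scaled by modulation depth). Absolute plus
#' relative refractoriness is applied by sequential thinning, and the
#' driving rate is pre-compensated so the realized rate matches the
#' envelope. The master seed spawns per-fiber, per-trial child seeds via
#' [childSeed()], so any fiber/trial is reproducible in isolation and the
#' same seed always yields identical output.
#'
#' @param stim a \code{StimulusDescriptor}.
#' @param p an \code{ANSurrogateParameters}.
#' @param nFibers number of fibers.
#' @param nTrials trials per fiber.
#' @param seed master seed (integer).
#' @param stream integer stream id kept distinct across protocol stages.
#' @param dt envelope resolution (ms).
#' @return list of \code{SpikeTrains}, one per fiber.
#' @examples
#' trains <- generateANTrains(toneStimulus(350, 70), nFibers = 2,
#'                            nTrials = 3, seed = 1)
#' nSpikes(trains[[1]])
#' @export
generateANTrains <- function(stim, p = ANSurrogateParameters(), nFibers,
                             nTrials, seed, stream = 0L, dt = 0.01) {
  stopifnot(nFibers >= 1, nTrials >= 1)
  env <- rateEnvelope(stim, p, dt)
  inflate <- anInflationFun(p, maxRate = max(env, p@spontRate, 1))
  driveEnv <- inflate(env)
  lockFreq <- NULL; targetVS <- 0
  if (stim@kind == "tone") {
    lockFreq <- stim@frequency
    targetVS <- anTargetVS(stim@frequency, p)
  } else if (stim@kind == "sam") {
    lockFreq <- stim@modFrequency
    targetVS <- anTargetVS(stim@modFrequency, p) * stim@modDepth
  }
  lapply(seq_len(nFibers), function(f) {
    trials <- vector("list", nTrials)
    for (tr in seq_len(nTrials)) {
      set.seed(childSeed(seed, fiber = f, trial = tr, stream = stream))
      trials[[tr]] <- drawFiberTrial(driveEnv, dt, stim@duration, lockFreq,
                                     targetVS, p)
    }
    new("SpikeTrains", trials = trials, trialDuration = stim@duration,
        meta = list(stimulus = stim@kind, frequency = stim@frequency,
                    level = stim@level, fiber = f, seed = seed,
                    stream = stream, source = "an_surrogate"))
  })
}

#' Load auditory-nerve spike trains from a spike-time file
#'
#' Adapter for externally produced AN spike trains in the delimited
#' spike-time format (columns \code{trial}, \code{fiber}, \code{time_ms};
#' see [writeSpikeFile()]). Trains are grouped by fiber and validated.
#'
#' @param path file path.
#' @param nFibers,nTrials expected counts; an error is raised on mismatch.
#' @param trialDuration trial duration in ms; defaults to the ceiling of the
#'   largest spike time.
#' @return list of \code{SpikeTrains}, one per fiber.
#' @export
loadANTrains <- function(path, nFibers, nTrials, trialDuration = NULL) {
  df <- readSpikeFile(path)
  fib <- sort(unique(df$fiber))
  if (nrow(df) && length(fib) != nFibers)
    stop(sprintf("expected %d fibers, file has %d", nFibers, length(fib)))
  if (nrow(df) && max(df$trial) > nTrials)
    stop(sprintf("file has trial ids above the expected %d", nTrials))
  if (is.null(trialDuration))
    trialDuration <- if (nrow(df)) ceiling(max(df$time_ms)) else 25
  lapply(seq_len(nFibers), function(f) {
    sub <- df[df$fiber == (if (length(fib)) fib[f] else f), , drop = FALSE]
    trials <- lapply(seq_len(nTrials), function(tr)
      sort(sub$time_ms[sub$trial == tr]))
    new("SpikeTrains", trials = trials, trialDuration = trialDuration,
        meta = list(source = path, fiber = f))
  })
}
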