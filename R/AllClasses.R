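#' @import methods
NULL

#' Parameters of the adaptive coincidence counting GBC model
#'
#' The model has six parameters: the number of excitatory auditory-nerve
#' inputs \code{mE}, the duration \code{wE} (ms, the "coincidence window")
#' and relative amplitude \code{aE} of each rectangular input count, the
#' absolute refractory period \code{tR} (ms), and the time constant \code{tA}
#' (ms) and strength \code{sA} of threshold adaptation. Amplitudes are
#' expressed relative to the static threshold, which is fixed at 1.
#'
#' @slot mE integer(1), number of excitatory input fibers (>= 1).
#' @slot wE numeric(1), coincidence window in ms (> 0).
#' @slot aE numeric(1), input amplitude relative to static threshold (> 0).
#' @slot tR numeric(1), absolute refractory period in ms (>= 0).
#' @slot tA numeric(1), adaptation time constant in ms (> 0).
#' @slot sA numeric(1), adaptation strength (>= 0).
#'
#' @seealso [GBCParameters()], [defaultParameters()]
#' @exportClass GBCParameters
setClass("GBCParameters",
  representation(mE = "integer", wE = "numeric", aE = "numeric",
                 tR = "numeric", tA = "numeric", sA = "numeric"),
  prototype(mE = 20L, wE = 0.32, aE = 0.40, tR = 1.20, tA = 0.25, sA = 0.80))

setValidity("GBCParameters", function(object) {
  msg <- character(0)
  for (s in c("mE", "wE", "aE", "tR", "tA", "sA")) {
    x <- slot(object, s)
    if (length(x) != 1L || is.na(x) || !is.finite(as.numeric(x)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (!length(msg)) {
    if (object@mE < 1L) msg <- c(msg, "mE must be >= 1")
    if (object@wE <= 0) msg <- c(msg, "wE must be > 0")
    if (object@aE <= 0) msg <- c(msg, "aE must be > 0")
    if (object@tR < 0)  msg <- c(msg, "tR must be >= 0")
    if (object@tA <= 0) msg <- c(msg, "tA must be > 0")
    if (object@sA < 0)  msg <- c(msg, "sA must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct GBC model parameters
#'
#' @param mE,wE,aE,tR,tA,sA model parameters; see
#'   \code{\linkS4class{GBCParameters}}. Defaults are the reference
#'   ("default") instance used throughout: 20 inputs, 0.32 ms window,
#'   amplitude 0.40, 1.20 ms refractory period, 0.25 ms adaptation time
#'   constant, adaptation strength 0.80.
#' @return A \code{GBCParameters} object.
#' @examples
#' GBCParameters(mE = 12, sA = 1.0)
#' @export
GBCParameters <- function(mE = 20, wE = 0.32, aE = 0.40,
                          tR = 1.20, tA = 0.25, sA = 0.80) {
  new("GBCParameters", mE = as.integer(round(mE)), wE = as.numeric(wE),
      aE = as.numeric(aE), tR = as.numeric(tR), tA = as.numeric(tA),
      sA = as.numeric(sA))
}

#' The default (reference) GBC model instance
#'
#' Returns the parameter set of the reference PL_N-type instance: the median
#' of the accepted population at 20 inputs, used for all single-instance
#' illustrations.
#' @return A \code{GBCParameters} object.
#' @export
defaultParameters <- function() GBCParameters()

setMethod("show", "GBCParameters", function(object) {
  cat("GBCParameters:",
      sprintf("mE=%d, wE=%.2f ms, aE=%.2f, tR=%.2f ms, tA=%.2f ms, sA=%.2f\n",
              object@mE, object@wE, object@aE, object@tR, object@tA,
              object@sA))
})

#' Simulation configuration
#'
#' @slot dt numeric(1), time step in ms (default 0.01).
#' @slot duration numeric(1), trial duration in ms.
#' @slot initialThetaD numeric(1), initial dynamic threshold (default 0).
#'
#' @details The coincidence window and refractory period are quantized onto
#' the \code{dt} grid by round-half-up (the window to at least one step).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(dt = "numeric", duration = "numeric",
                 initialThetaD = "numeric"),
  prototype(dt = 0.01, duration = 25, initialThetaD = 0))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@initialThetaD < 0) msg <- c(msg, "initialThetaD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param dt time step (ms).
#' @param duration trial duration (ms).
#' @param initialThetaD initial dynamic threshold.
#' @return A \code{SimulationConfig} object.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(dt = 0.01, duration = 25, initialThetaD = 0) {
  new("SimulationConfig", dt = dt, duration = duration,
      initialThetaD = initialThetaD)
}

#' Per-trial spike-time collections
#'
#' Holds one spike-time vector (ms, relative to trial onset) per trial,
#' together with the trial duration and free-form provenance metadata.
#'
#' @slot trials list of numeric vectors, strictly increasing spike times in
#'   ms within \code{[0, trialDuration]}.
#' @slot trialDuration numeric(1), ms.
#' @slot meta list, provenance (stimulus, seed, source, ...).
#' @exportClass SpikeTrains
setClass("SpikeTrains",
  representation(trials = "list", trialDuration = "numeric", meta = "list"),
  prototype(trials = list(), trialDuration = 25, meta = list()))

setValidity("SpikeTrains", function(object) {
  if (length(object@trialDuration) != 1L || object@trialDuration <= 0)
    return("trialDuration must be a positive scalar")
  for (i in seq_along(object@trials)) {
    t <- object@trials[[i]]
    if (!is.numeric(t)) return(sprintf("trial %d is not numeric", i))
    if (length(t)) {
      if (any(t < 0 | t > object@trialDuration))
        return(sprintf("trial %d has spike times outside [0, duration]", i))
      if (any(diff(t) <= 0))
        return(sprintf("trial %d spike times are not strictly increasing", i))
    }
  }
  TRUE
})

#' @param trials list of per-trial spike-time vectors (ms).
#' @param trialDuration trial duration (ms).
#' @param meta list of provenance metadata.
#' @return A \code{SpikeTrains} object.
#' @rdname SpikeTrains-class
#' @export
SpikeTrains <- function(trials, trialDuration, meta = list()) {
  new("SpikeTrains", trials = lapply(trials, as.numeric),
      trialDuration = as.numeric(trialDuration), meta = meta)
}

setMethod("show", "SpikeTrains", function(object) {
  n <- vapply(object@trials, length, integer(1))
  cat(sprintf("SpikeTrains: %d trial(s) of %.4g ms, %d spike(s) total\n",
              length(n), object@trialDuration, sum(n)))
})

#' Parametric description of a sound protocol
#'
#' @slot kind character(1), one of "silence", "tone", "sam".
#' @slot frequency numeric(1), Hz (tone frequency or SAM carrier).
#' @slot level numeric(1), dB SPL.
#' @slot duration numeric(1), ms.
#' @slot riseFall numeric(1), linear rise/fall ramp duration in ms.
#' @slot modFrequency numeric(1), Hz (SAM only).
#' @slot modDepth numeric(1), modulation depth fraction in [0, 1] (SAM only).
#' @slot cf numeric(1), characteristic frequency of the driven fibers (Hz).
#' @exportClass StimulusDescriptor
setClass("StimulusDescriptor",
  representation(kind = "character", frequency = "numeric", level = "numeric",
                 duration = "numeric", riseFall = "numeric",
                 modFrequency = "numeric", modDepth = "numeric",
                 cf = "numeric"),
  prototype(kind = "silence", frequency = 0, level = 0, duration = 25,
            riseFall = 0, modFrequency = 0, modDepth = 0, cf = 0))

setValidity("StimulusDescriptor", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("silence", "tone", "sam"))
    msg <- c(msg, "kind must be one of 'silence', 'tone', 'sam'")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@modDepth < 0 || object@modDepth > 1)
    msg <- c(msg, "modDepth must be in [0, 1]")
  if (2 * object@riseFall > object@duration)
    msg <- c(msg, "rise/fall ramps must fit within the stimulus duration")
  if (object@kind != "silence" && object@frequency <= 0)
    msg <- c(msg, "frequency must be > 0 for tone/sam")
  if (object@kind == "sam" && object@modFrequency <= 0)
    msg <- c(msg, "modFrequency must be > 0 for sam")
  if (length(msg)) msg else TRUE
})

#' Construct a stimulus descriptor
#'
#' @param kind "silence", "tone" or "sam".
#' @param frequency tone frequency or SAM carrier frequency (Hz).
#' @param level sound level (dB SPL).
#' @param duration stimulus duration (ms). The default tone burst is 25 ms.
#' @param riseFall linear rise/fall ramp (ms); 3.9 ms for tone bursts.
#' @param modFrequency SAM modulation frequency (Hz).
#' @param modDepth SAM modulation depth in [0, 1].
#' @param cf characteristic frequency of the driven fibers (Hz); defaults to
#'   \code{frequency}.
#' @return A \code{StimulusDescriptor}.
#' @examples
#' toneStimulus(350, 70)
#' @export
StimulusDescriptor <- function(kind, frequency = 0, level = 0, duration = 25,
                               riseFall = 0, modFrequency = 0, modDepth = 0,
                               cf = frequency) {
  new("StimulusDescriptor", kind = kind, frequency = as.numeric(frequency),
      level = as.numeric(level), duration = as.numeric(duration),
      riseFall = as.numeric(riseFall),
      modFrequency = as.numeric(modFrequency),
      modDepth = as.numeric(modDepth), cf = as.numeric(cf))
}

#' @rdname StimulusDescriptor
#' @export
toneStimulus <- function(frequency, level = 70, duration = 25,
                         riseFall = 3.9, cf = frequency) {
  StimulusDescriptor("tone", frequency = frequency, level = level,
                     duration = duration, riseFall = riseFall, cf = cf)
}

#' @rdname StimulusDescriptor
#' @export
silenceStimulus <- function(duration = 1000) {
  StimulusDescriptor("silence", duration = duration)
}

#' @rdname StimulusDescriptor
#' @export
samStimulus <- function(frequency, level, modFrequency = 100, modDepth = 1,
                        duration = 600, riseFall = 3.9, cf = frequency) {
  StimulusDescriptor("sam", frequency = frequency, level = level,
                     duration = duration, riseFall = riseFall,
                     modFrequency = modFrequency, modDepth = modDepth,
                     cf = cf)
}

setMethod("show", "StimulusDescriptor", function(object) {
  cat(sprintf("StimulusDescriptor: %s", object@kind))
  if (object@kind != "silence")
    cat(sprintf(" %g Hz @ %g dB SPL (cf %g Hz)", object@frequency,
                object@level, object@cf))
  if (object@kind == "sam")
    cat(sprintf(", mod %g Hz depth %g", object@modFrequency, object@modDepth))
  cat(sprintf(", %g ms\n", object@duration))
})

#' Parameters of the auditory-nerve surrogate generator
#'
#' A phenomenological stand-in for a full auditory-periphery model. It
#' emulates the input statistics the GBC model expects from high
#' spontaneous-rate AN fibers: ~70 spikes/s spontaneous rate, an
#' onset-adapted driven rate that saturates above ~40 dB SPL, phase-locking
#' that decays with frequency above ~1 kHz, absolute plus relative
#' refractoriness, and a V-shaped frequency tuning with a capped
#' low-frequency "tail" so that intense low-frequency tones drive high-CF
#' fibers.
#'
#' @slot spontRate spikes/s (default 70).
#' @slot maxDrivenRate saturated steady-state rate, spikes/s (default 250).
#' @slot rateThresholdLevel,rateSaturationLevel dB SPL endpoints of the
#'   sigmoid rate-level function (defaults 0 and 40).
#' @slot onsetPeakRatio onset multiplier of the driven rate (default 3).
#' @slot onsetTau exponential onset-adaptation time constant, ms (default 5).
#' @slot absRefractory absolute refractory period, ms (default 0.45).
#' @slot relRefractory relative refractory recovery constant, ms
#'   (default 0.5125).
#' @slot vsMax maximal attainable vector strength at low frequency
#'   (default 0.85).
#' @slot vsCornerFreq,vsSlope corner frequency (Hz) and slope of the
#'   frequency -> target-VS decay curve (defaults 1100 Hz and 2.5).
#' @slot tuneSlopeLo,tuneSlopeHi tuning-filter attenuation slopes below and
#'   above CF, dB/octave (defaults 40 and 120).
#' @slot tailThresholdShift cap on below-CF attenuation, dB (default 40);
#'   an extra threshold shift for the low-frequency tail response.
#' @exportClass ANSurrogateParameters
setClass("ANSurrogateParameters",
  representation(spontRate = "numeric", maxDrivenRate = "numeric",
                 rateThresholdLevel = "numeric",
                 rateSaturationLevel = "numeric",
                 onsetPeakRatio = "numeric", onsetTau = "numeric",
                 absRefractory = "numeric", relRefractory = "numeric",
                 vsMax = "numeric", vsCornerFreq = "numeric",
                 vsSlope = "numeric", tuneSlopeLo = "numeric",
                 tuneSlopeHi = "numeric", tailThresholdShift = "numeric"),
  prototype(spontRate = 70, maxDrivenRate = 250, rateThresholdLevel = 0,
            rateSaturationLevel = 40, onsetPeakRatio = 3, onsetTau = 5,
            absRefractory = 0.45, relRefractory = 0.5125, vsMax = 0.85,
            vsCornerFreq = 1100, vsSlope = 2.5, tuneSlopeLo = 40,
            tuneSlopeHi = 120, tailThresholdShift = 40))

setValidity("ANSurrogateParameters", function(object) {
  msg <- character(0)
  if (object@spontRate < 0 || object@maxDrivenRate < 0)
    msg <- c(msg, "rates must be >= 0")
  if (object@absRefractory < 0 || object@relRefractory < 0)
    msg <- c(msg, "refractory parameters must be >= 0")
  if (object@vsMax < 0 || object@vsMax >= 1)
    msg <- c(msg, "vsMax must be in [0, 1)")
  if (object@onsetTau <= 0) msg <- c(msg, "onsetTau must be > 0")
  if (object@onsetPeakRatio < 1) msg <- c(msg, "onsetPeakRatio must be >= 1")
  if (object@rateSaturationLevel <= object@rateThresholdLevel)
    msg <- c(msg, "rateSaturationLevel must exceed rateThresholdLevel")
  if (length(msg)) msg else TRUE
})

#' Construct auditory-nerve surrogate parameters
#'
#' @param ... named slot overrides; see
#'   \code{\linkS4class{ANSurrogateParameters}}.
#' @return An \code{ANSurrogateParameters} object.
#' @examples
#' ANSurrogateParameters(spontRate = 50)
#' @export
ANSurrogateParameters <- function(...) new("ANSurrogateParameters", ...)

setMethod("show", "ANSurrogateParameters", function(object) {
  cat(sprintf(paste0("ANSurrogateParameters: spont %g/s, max driven %g/s,",
                     " refractory %g+%g ms, vsMax %g @ corner %g Hz\n"),
              object@spontRate, object@maxDrivenRate, object@absRefractory,
              object@relRefractory, object@vsMax, object@vsCornerFreq))
})

#' Six-dimensional model parameter grid
#'
#' Ordered value lists for the six model parameters; instances are indexed
#' bijectively with the Cartesian product (the first dimension varies
#' fastest).
#'
#' @slot values named list of six sorted numeric vectors, in the order
#'   mE, wE, aE, tR, tA, sA.
#' @exportClass ParameterGrid
setClass("ParameterGrid", representation(values = "list"))

setValidity("ParameterGrid", function(object) {
  nm <- c("mE", "wE", "aE", "tR", "tA", "sA")
  if (!identical(names(object@values), nm))
    return("grid values must be named mE, wE, aE, tR, tA, sA in that order")
  for (d in nm) {
    v <- object@values[[d]]
    if (!length(v)) return(sprintf("dimension '%s' is empty", d))
    if (is.unsorted(v, strictly = TRUE))
      return(sprintf("dimension '%s' must be strictly increasing", d))
  }
  TRUE
})

setMethod("show", "ParameterGrid", function(object) {
  n <- vapply(object@values, length, integer(1))
  cat(sprintf("ParameterGrid: %s = %d instances\n",
              paste(n, collapse = " x "), prod(n)))
})

#' Spike-train histogram
#'
#' @slot kind character(1): "psth", "period" or "isih".
#' @slot binEdges numeric, bin edges (ms, or cycle fraction for period
#'   histograms).
#' @slot counts numeric, raw counts per bin.
#' @slot smoothedRate numeric, five-point triangular smoothed rate in
#'   spikes/s (PSTH only; otherwise length 0).
#' @slot nTrials integer(1), number of trials the counts pool over.
#' @exportClass SpikeHistogram
setClass("SpikeHistogram",
  representation(kind = "character", binEdges = "numeric",
                 counts = "numeric", smoothedRate = "numeric",
                 nTrials = "integer"))

setValidity("SpikeHistogram", function(object) {
  if (!object@kind %in% c("psth", "period", "isih"))
    return("kind must be 'psth', 'period' or 'isih'")
  if (length(object@counts) != length(object@binEdges) - 1L)
    return("counts must have one fewer element than binEdges")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

setMethod("show", "SpikeHistogram", function(object) {
  cat(sprintf("SpikeHistogram (%s): %d bins, %g events, %d trial(s)\n",
              object@kind, length(object@counts), sum(object@counts),
              object@nTrials))
})
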