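# Fixtures built in code: deterministic spike trains and constructed PSTH
# rate traces.

# n fibers that all spike at exactly the given times (a synchronized volley)
volleyFibers <- function(times, nFibers = 3, duration = 10) {
  lapply(seq_len(nFibers), function(i)
    SpikeTrains(list(times), trialDuration = duration))
}

# single-trial train with given spike times
train1 <- function(times, duration = NULL) {
  if (is.null(duration)) duration <- max(25, if (length(times))
    max(times) + 1 else 0)
  SpikeTrains(list(times), trialDuration = duration)
}

# strictly periodic train: n spikes at interval `period` ms from `start`
periodicTrain <- function(period, n, start = 10, duration = NULL) {
  tt <- start + period * (seq_len(n) - 1)
  if (is.null(duration)) duration <- max(tt) + period
  train1(tt, duration)
}

# wrap a hand-constructed smoothed rate trace (spikes/s, 0.1 ms bins) in a
# SpikeHistogram so the feature extractor can run on it
rateTraceHistogram <- function(rate, bin = 0.1) {
  n <- length(rate)
  new("SpikeHistogram", kind = "psth",
      binEdges = seq(0, n * bin, by = bin),
      counts = rep(0, n), smoothedRate = rate, nTrials = 1L)
}

# canonical 25-ms traces (250 bins at 0.1 ms), sustained rate 200 spikes/s
plnTrace <- function(sustained = 200, peak = 1000, notchBins = 5,
                     notchRate = 50) {
  r <- rep(sustained, 250)
  r[9:11] <- c(600, peak, 600)              # onset peak at ~1 ms
  r[12:(11 + notchBins)] <- notchRate       # first notch
  r
}

chopperTrace <- function(secondPeak = 600) {
  r <- plnTrace()
  r[17:19] <- c(secondPeak, secondPeak, secondPeak)  # second peak ~1.8 ms
  r[20:24] <- 50                                     # second notch 0.5 ms
  r
}

# random Poisson fibers on a fixed seed, snapped-friendly
poissonFibers <- function(rate, nFibers, duration, seed) {
  set.seed(seed)
  lapply(seq_len(nFibers), function(i) {
    n <- rpois(1, rate * duration / 1000)
    SpikeTrains(list(sort(runif(n, 0, duration))), trialDuration = duration)
  })
}
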