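# Spike-train output measures: rates, regularity, phase-locking,
# entrainment, and histograms. Undefined measures are returned as NA (an
# explicit flag), never as silent zeros.

#' Restrict spikes to the sustained analysis window
#'
#' Keeps the spikes in \code{[start, end)} of every trial. The defaults
#' select the sustained part of a 25 ms tone-burst response, 10 to 25 ms
#' after stimulus onset.
#'
#' @param spikes a \code{SpikeTrains}.
#' @param start,end window in ms (half-open).
#' @return a \code{SpikeTrains} with the per-trial structure preserved.
#' @export
sustainedWindow <- function(spikes, start = 10, end = 25) {
  stopifnot(end > start)
  new("SpikeTrains",
      trials = lapply(spikes@trials, function(t) t[t >= start & t < end]),
      trialDuration = spikes@trialDuration,
      meta = c(spikes@meta, list(window = c(start, end))))
}

#' Vector strength
#'
#' Circular-mean resultant length of the pooled spike phases at a reference
#' frequency: \eqn{VS = (1/N) |\sum_k e^{2\pi i f t_k}|}. 1 means perfect
#' phase-locking, 0 no locking.
#'
#' @param spikes a \code{SpikeTrains} (typically already windowed with
#'   [sustainedWindow()]).
#' @param f reference frequency (Hz).
#' @return VS in [0, 1]; \code{NA} when there are no spikes.
#' @export
vectorStrength <- function(spikes, f) {
  stopifnot(f > 0)
  tt <- unlist(spikes@trials, use.names = FALSE)
  if (!length(tt)) return(NA_real_)
  ph <- 2 * pi * f * tt / 1000
  Mod(mean(complex(modulus = 1, argument = ph)))
}

# Within-trial interspike intervals, pooled; never across trial boundaries.
pooledISIs <- function(spikes) {
  unlist(lapply(spikes@trials, function(t)
    if (length(t) >= 2) diff(t) else numeric(0)), use.names = FALSE)
}

#' Entrainment index
#'
#' Fraction of within-trial interspike intervals lying in
#' \code{(0.5/f, 1.5/f)}, i.e. within half a cycle of the stimulus period.
#' 1 indicates one spike on every stimulus cycle.
#'
#' @inheritParams vectorStrength
#' @return EI in [0, 1]; \code{NA} when there are no ISIs.
#' @export
entrainmentIndex <- function(spikes, f) {
  stopifnot(f > 0)
  isi <- pooledISIs(spikes)
  if (!length(isi)) return(NA_real_)
  period <- 1000 / f
  mean(isi > 0.5 * period & isi < 1.5 * period)
}

#' Modified coefficient of variation of interspike intervals
#'
#' \eqn{CV' = \sigma_{ISI} / (\mu_{ISI} - \mu_0)} with dead-time correction
#' \eqn{\mu_0} (default 0.5 ms). \eqn{\sigma_{ISI}} is the population
#' (divide-by-N) standard deviation of the within-trial ISIs pooled across
#' trials.
#'
#' @param spikes a \code{SpikeTrains}.
#' @param mu0 dead-time correction (ms).
#' @return CV'; \code{NA} when fewer than 2 ISIs are available or
#'   \eqn{\mu_{ISI} \le \mu_0}.
#' @export
cvPrime <- function(spikes, mu0 = 0.5) {
  isi <- pooledISIs(spikes)
  if (length(isi) < 2) return(NA_real_)
  mu <- mean(isi)
  if (mu <= mu0) return(NA_real_)
  sigma <- sqrt(mean((isi - mu)^2))
  sigma / (mu - mu0)
}

#' Peristimulus time histogram
#'
#' Bins the spikes of all trials at \code{bin} ms resolution from 0 to the
#' trial duration. With \code{smooth = TRUE} the counts are convolved with
#' the five-point triangular kernel (1,2,3,2,1)/9 (which preserves the total
#' count for interior spikes) and converted to a rate in spikes/s by
#' dividing by \code{nTrials * bin}.
#'
#' @param spikes a \code{SpikeTrains}.
#' @param bin bin width (ms), default 0.1.
#' @param smooth logical, apply triangular smoothing.
#' @return a \code{SpikeHistogram} of kind "psth".
#' @export
computePSTH <- function(spikes, bin = 0.1, smooth = TRUE) {
  nt <- max(1L, nTrials(spikes))
  edges <- seq(0, spikes@trialDuration + bin * 1e-9, by = bin)
  if (edges[length(edges)] < spikes@trialDuration)
    edges <- c(edges, edges[length(edges)] + bin)
  tt <- unlist(spikes@trials, use.names = FALSE)
  cnt <- if (length(tt))
    as.numeric(tabulate(findInterval(tt, edges, rightmost.closed = TRUE),
                        nbins = length(edges) - 1L))
  else rep(0, length(edges) - 1L)
  sm <- numeric(0)
  if (smooth) {
    sc <- smoothTriangular(cnt)
    sm <- sc / (nt * bin / 1000)
  }
  new("SpikeHistogram", kind = "psth", binEdges = edges, counts = cnt,
      smoothedRate = sm, nTrials = as.integer(nt))
}

# Five-point triangular smoothing with zero padding at the edges.
smoothTriangular <- function(x) {
  k <- c(1, 2, 3, 2, 1) / 9
  n <- length(x)
  if (n < 5) {
    xp <- c(0, 0, x, 0, 0)
    return(vapply(seq_len(n), function(i) sum(xp[i:(i + 4)] * rev(k)),
                  numeric(1)))
  }
  as.numeric(stats::filter(c(0, 0, x, 0, 0), k, sides = 2))[3:(n + 2)]
}

#' Period histogram
#'
#' Folds the pooled spike times by the stimulus period and bins the phase in
#' cycle fractions.
#'
#' @param spikes a \code{SpikeTrains}.
#' @param f reference frequency (Hz).
#' @param nBins number of phase bins.
#' @return a \code{SpikeHistogram} of kind "period" with bin edges in cycle
#'   fraction [0, 1].
#' @export
periodHistogram <- function(spikes, f, nBins = 32) {
  stopifnot(f > 0, nBins >= 1)
  tt <- unlist(spikes@trials, use.names = FALSE)
  ph <- (tt * f / 1000) %% 1
  edges <- seq(0, 1, length.out = nBins + 1)
  cnt <- if (length(ph))
    as.numeric(tabulate(pmin(floor(ph * nBins) + 1L, nBins), nbins = nBins))
  else rep(0, nBins)
  new("SpikeHistogram", kind = "period", binEdges = edges, counts = cnt,
      smoothedRate = numeric(0), nTrials = as.integer(max(1L,
      nTrials(spikes))))
}

#' Interspike-interval histogram
#'
#' Histogram of within-trial ISIs at \code{bin} ms resolution.
#'
#' @param spikes a \code{SpikeTrains}.
#' @param bin bin width (ms).
#' @param maxISI upper edge (ms); defaults to the largest ISI.
#' @return a \code{SpikeHistogram} of kind "isih".
#' @export
isiHistogram <- function(spikes, bin = 0.1, maxISI = NULL) {
  isi <- pooledISIs(spikes)
  if (is.null(maxISI)) maxISI <- if (length(isi)) max(isi) else bin
  edges <- seq(0, maxISI + bin, by = bin)
  cnt <- if (length(isi))
    as.numeric(tabulate(findInterval(isi, edges, rightmost.closed = TRUE),
                        nbins = length(edges) - 1L))
  else rep(0, length(edges) - 1L)
  new("SpikeHistogram", kind = "isih", binEdges = edges, counts = cnt,
      smoothedRate = numeric(0), nTrials = as.integer(max(1L,
      nTrials(spikes))))
}

#' Spontaneous and sound-driven rates
#'
#' The spontaneous rate is the total spike count of the silence simulation
#' divided by its total simulated time. The driven rate is computed from the
#' sustained window of the driven response (default 10-25 ms).
#'
#' @param silenceSpikes \code{SpikeTrains} simulated without stimulus.
#' @param drivenSpikes \code{SpikeTrains} of the driven response.
#' @param window sustained window (ms), default \code{c(10, 25)}.
#' @return named numeric vector \code{c(sr =, dr =)} in spikes/s.
#' @export
spontAndDrivenRates <- function(silenceSpikes, drivenSpikes,
                                window = c(10, 25)) {
  totalS <- nTrials(silenceSpikes) * trialDuration(silenceSpikes) / 1000
  sr <- if (totalS > 0) nSpikes(silenceSpikes) / totalS else NA_real_
  sust <- sustainedWindow(drivenSpikes, window[1], window[2])
  totalD <- nTrials(drivenSpikes) * (window[2] - window[1]) / 1000
  dr <- if (totalD > 0) nSpikes(sust) / totalD else NA_real_
  c(sr = sr, dr = dr)
}

#' Bundle of response metrics for one driven condition
#'
#' Convenience wrapper computing DR, CV', VS and EI on the sustained window
#' of one driven response.
#'
#' @param drivenSpikes \code{SpikeTrains} of the driven response.
#' @param f stimulus (or modulation) frequency in Hz for VS/EI.
#' @param window sustained analysis window (ms).
#' @param mu0 dead-time correction for CV' (ms).
#' @return named list with \code{dr}, \code{cvPrime}, \code{vs}, \code{ei},
#'   \code{nSpikesUsed}.
#' @export
responseMetrics <- function(drivenSpikes, f, window = c(10, 25), mu0 = 0.5) {
  sust <- sustainedWindow(drivenSpikes, window[1], window[2])
  totalD <- nTrials(drivenSpikes) * (window[2] - window[1]) / 1000
  list(dr = nSpikes(sust) / totalD,
       cvPrime = cvPrime(sust, mu0),
       vs = vectorStrength(sust, f),
       ei = entrainmentIndex(sust, f),
       nSpikesUsed = nSpikes(sust))
}
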