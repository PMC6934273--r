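# PSTH shape features and the PL_N / On_L acceptance rules, with chopper
# and dipper rejection.

#' Extract PSTH shape features
#'
#' Works on a smoothed PSTH (0.1 ms bins). The first peak is the global
#' maximum of the smoothed rate in the onset region (0-5 ms). Notches are
#' contiguous spans after the first peak where the smoothed rate falls
#' below 90% of the sustained rate; the first such span is the first notch
#' (width measured at the 90% level), the second span the second notch. The
#' second peak is the maximum of the rate between the two spans (or between
#' the first span and the start of the sustained window). Absent features
#' are reported with width 0 / rate NA.
#'
#' @param psth a \code{SpikeHistogram} of kind "psth" with a smoothed rate.
#' @param sustainedRate spikes/s; defaults to the mean smoothed rate over
#'   \code{sustainedWindow} ms.
#' @param onsetRegion time span (ms) searched for the first peak.
#' @param sustainedWindow window (ms) defining the sustained rate.
#' @return a list with \code{firstPeakRate}, \code{firstPeakTime},
#'   \code{firstNotchMinRate}, \code{firstNotchWidth},
#'   \code{secondPeakRate}, \code{secondNotchWidth}, \code{sustainedRate}.
#' @export
extractPSTHFeatures <- function(psth, sustainedRate = NULL,
                                onsetRegion = c(0, 5),
                                sustainedWindow = c(10, 25)) {
  stopifnot(is(psth, "SpikeHistogram"), psth@kind == "psth",
            length(psth@smoothedRate) > 0)
  rate <- psth@smoothedRate
  mid <- binCenters(psth)
  bin <- psth@binEdges[2] - psth@binEdges[1]
  if (is.null(sustainedRate)) {
    inSust <- mid >= sustainedWindow[1] & mid < sustainedWindow[2]
    sustainedRate <- if (any(inSust)) mean(rate[inSust]) else mean(rate)
  }
  onset <- which(mid >= onsetRegion[1] & mid <= onsetRegion[2])
  if (!length(onset)) onset <- seq_along(rate)
  pk <- onset[which.max(rate[onset])]
  feats <- list(firstPeakRate = rate[pk], firstPeakTime = mid[pk],
                firstNotchMinRate = NA_real_, firstNotchWidth = 0,
                secondPeakRate = NA_real_, secondNotchWidth = 0,
                sustainedRate = sustainedRate)
  thr <- 0.9 * sustainedRate
  after <- if (pk < length(rate)) (pk + 1L):length(rate) else integer(0)
  if (!length(after) || thr <= 0) {
    if (length(after)) feats$firstNotchMinRate <- min(rate[after])
    return(feats)
  }
  below <- rate[after] < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- which(r$values)
  if (!length(spans)) {
    feats$firstNotchMinRate <- min(rate[after])
    return(feats)
  }
  s1 <- after[starts[spans[1]]:ends[spans[1]]]
  feats$firstNotchMinRate <- min(rate[s1])
  feats$firstNotchWidth <- length(s1) * bin
  # region between first and second sub-threshold spans (or up to the
  # sustained window) holds the second peak, if any
  afterNotch <- if (max(s1) < length(rate)) (max(s1) + 1L):length(rate)
                else integer(0)
  if (length(spans) >= 2) {
    s2 <- after[starts[spans[2]]:ends[spans[2]]]
    feats$secondNotchWidth <- length(s2) * bin
    between <- setdiff(afterNotch[afterNotch < min(s2)], integer(0))
    if (length(between)) feats$secondPeakRate <- max(rate[between])
  } else {
    upTo <- afterNotch[mid[afterNotch] < sustainedWindow[1]]
    if (length(upTo)) {
      cand <- max(rate[upTo])
      # only report a second peak if the recovery overshoots the sustained
      # level; a monotone recovery into the sustained rate is not a peak
      if (cand > sustainedRate * 1.05) feats$secondPeakRate <- cand
    }
  }
  feats
}

#' Apply the PSTH shape criteria P1-P4
#'
#' P1: the first notch is below 90% of the sustained rate. P2: the first
#' notch width (measured at 90% of the sustained rate) is between 0.15 and
#' 1.5 ms. P3: the second peak rate is below half of the first peak rate
#' (absent second peak passes). P4: the second notch is non-existent or
#' shorter than 0.85 ms. P2 and P4 reject dip-type responses (long pauses),
#' P3 and P4 reject choppers.
#'
#' @param f feature list from [extractPSTHFeatures()].
#' @return named logical vector \code{c(P1 =, P2 =, P3 =, P4 =)}.
#' @export
checkPSTHCriteria <- function(f) {
  p1 <- !is.na(f$firstNotchMinRate) &&
    f$firstNotchMinRate < 0.9 * f$sustainedRate
  p2 <- f$firstNotchWidth >= 0.15 && f$firstNotchWidth <= 1.5
  p3 <- is.na(f$secondPeakRate) ||
    f$secondPeakRate < 0.5 * f$firstPeakRate
  p4 <- f$secondNotchWidth < 0.85
  c(P1 = p1, P2 = p2, P3 = p3, P4 = p4)
}

#' Classify one model instance from its response metrics
#'
#' Applies the GBC acceptance rules: spontaneous rate below 30 spikes/s;
#' at 7000 Hz / 70 dB SPL a sustained driven rate of at least 150 spikes/s
#' (PL_N) or in [50, 150) (On_L) with CV' in [0.65, 0.95] and a PL_N-shaped
#' PSTH (P1-P4); at 350 Hz / 70 dB SPL vector strength and entrainment
#' index above 0.9. Instances meeting the rate criteria but failing P3 are
#' labelled choppers; failing P2 or P4, dippers. Any undefined (NA) metric
#' rejects the instance.
#'
#' @param sr spontaneous rate (spikes/s).
#' @param dr sustained driven rate at 7000 Hz (spikes/s).
#' @param cvp modified coefficient of variation at 7000 Hz.
#' @param vs,ei vector strength and entrainment index at 350 Hz.
#' @param psthFlags logical vector P1-P4 from [checkPSTHCriteria()].
#' @return a list with \code{category} (one of \code{"PLN"}, \code{"ONL"},
#'   \code{"CHOPPER"}, \code{"DIPPER"}, \code{"OTHER"},
#'   \code{"REJECTED_RATES"}) and \code{flags}, the named logical vector of
#'   all per-criterion outcomes.
#' @export
classifyInstance <- function(sr, dr, cvp, vs, ei, psthFlags) {
  vals <- c(sr = sr, dr = dr, cvp = cvp, vs = vs, ei = ei)
  if (anyNA(vals) || anyNA(psthFlags)) {
    flags <- c(SR = FALSE, DR_PLN = FALSE, DR_ONL = FALSE, CV = FALSE,
               VS = FALSE, EI = FALSE, P1 = FALSE, P2 = FALSE, P3 = FALSE,
               P4 = FALSE)
    return(list(category = "REJECTED_RATES", flags = flags,
                reason = "undefined metric"))
  }
  flags <- c(SR = sr < 30,
             DR_PLN = dr >= 150,
             DR_ONL = dr >= 50 && dr < 150,
             CV = cvp >= 0.65 && cvp <= 0.95,
             VS = vs > 0.9,
             EI = ei > 0.9,
             psthFlags[c("P1", "P2", "P3", "P4")])
  ratesOk <- flags[["SR"]] && flags[["CV"]] && flags[["VS"]] && flags[["EI"]]
  drOk <- flags[["DR_PLN"]] || flags[["DR_ONL"]]
  pAll <- all(flags[c("P1", "P2", "P3", "P4")])
  category <-
    if (!ratesOk || !drOk) "REJECTED_RATES"
    else if (pAll && flags[["DR_PLN"]]) "PLN"
    else if (pAll) "ONL"
    else if (!flags[["P3"]]) "CHOPPER"
    else if (!flags[["P2"]] || !flags[["P4"]]) "DIPPER"
    else "OTHER"
  list(category = category, flags = flags)
}
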