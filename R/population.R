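# Six-dimensional parameter grid, population screening, dimensional
# stacking, frequency response areas and population validation protocols.

GRID_DIMS <- c("mE", "wE", "aE", "tR", "tA", "sA")

#' Build the model parameter grid
#'
#' The default value lists define the full screening grid:
#' \itemize{
#'   \item mE: 9, 12, 16, 20, 25, 30, 36
#'   \item wE: 0.08-0.80 ms in 0.08 ms steps (10 values)
#'   \item aE: 0.24-0.56 in 0.04 steps (9 values)
#'   \item tR: 0.70-1.50 ms in 0.10 ms steps (9 values)
#'   \item tA: 0.05-0.50 ms in 0.05 ms steps (10 values)
#'   \item sA: 0.40-1.30 in 0.10 steps (10 values)
#' }
#' for 7*10*9*9*10*10 = 567,000 instances in total.
#'
#' @param overrides named list of per-dimension value vectors replacing the
#'   defaults (names among mE, wE, aE, tR, tA, sA); each must be sorted and
#'   non-empty.
#' @return a \code{ParameterGrid}.
#' @examples
#' gridSize(buildGrid())                      # 567000
#' gridSize(buildGrid(list(mE = c(12, 20))))  # 162000
#' @export
buildGrid <- function(overrides = NULL) {
  values <- list(
    mE = c(9, 12, 16, 20, 25, 30, 36),
    wE = c(0.08, 0.16, 0.24, 0.32, 0.40, 0.48, 0.56, 0.64, 0.72, 0.80),
    aE = c(0.24, 0.28, 0.32, 0.36, 0.40, 0.44, 0.48, 0.52, 0.56),
    tR = c(0.70, 0.80, 0.90, 1.00, 1.10, 1.20, 1.30, 1.40, 1.50),
    tA = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50),
    sA = c(0.40, 0.50, 0.60, 0.70, 0.80, 0.90, 1.00, 1.10, 1.20, 1.30))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), GRID_DIMS)
    if (length(bad)) stop("unknown grid dimension(s): ",
                          paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      v <- sort(as.numeric(overrides[[nm]]))
      if (!length(v)) stop(sprintf("dimension '%s' is empty", nm))
      values[[nm]] <- v
    }
  }
  new("ParameterGrid", values = values)
}

#' Desk-scale screening grid
#'
#' Three values per dimension (the extremes and the default instance's
#' value), 3^6 = 729 instances. This is the default test profile; the full
#' grid of [buildGrid()] is the long-running mode.
#' @return a \code{ParameterGrid}.
#' @export
deskGrid <- function() {
  full <- gridValues(buildGrid())
  def <- parameterVector(defaultParameters())
  buildGrid(lapply(stats::setNames(GRID_DIMS, GRID_DIMS), function(d)
    unique(c(min(full[[d]]), def[[d]], max(full[[d]])))))
}

#' Instance id to grid indices and back
#'
#' Instance ids are 1-based and in bijection with the Cartesian product of
#' the six value lists; the first dimension (mE) varies fastest.
#'
#' @param grid a \code{ParameterGrid}.
#' @param id instance id(s) in 1..gridSize(grid).
#' @return for \code{instanceIndices}, an integer matrix (one row per id,
#'   columns mE..sA); for \code{instanceParameters} a \code{GBCParameters}
#'   (single id) and for \code{instanceId} the id(s).
#' @export
instanceIndices <- function(grid, id) {
  n <- vapply(grid@values, length, integer(1))
  if (any(id < 1 | id > prod(n))) stop("instance id out of range")
  r <- id - 1
  out <- matrix(0L, length(id), 6, dimnames = list(NULL, GRID_DIMS))
  for (d in seq_len(6)) {
    out[, d] <- as.integer(r %% n[d]) + 1L
    r <- r %/% n[d]
  }
  out
}

#' @rdname instanceIndices
#' @param idx integer vector (or matrix) of per-dimension indices.
#' @export
instanceId <- function(grid, idx) {
  n <- vapply(grid@values, length, integer(1))
  if (is.vector(idx)) idx <- matrix(idx, nrow = 1)
  if (any(idx < 1) || any(idx > rep(n, each = nrow(idx))))
    stop("grid index out of range")
  id <- rep(0, nrow(idx))
  for (d in 6:1) id <- id * n[d] + (idx[, d] - 1)
  id + 1
}

#' @rdname instanceIndices
#' @export
instanceParameters <- function(grid, id) {
  stopifnot(length(id) == 1L)
  ix <- instanceIndices(grid, id)[1, ]
  v <- grid@values
  GBCParameters(mE = v$mE[ix[1]], wE = v$wE[ix[2]], aE = v$aE[ix[3]],
                tR = v$tR[ix[4]], tA = v$tA[ix[5]], sA = v$sA[ix[6]])
}

# ---- selection battery -------------------------------------------------

# Shared AN input cache for one mE: pooled snapped steps for the three
# selection stimuli. Inputs are generated once per (mE, stimulus, seed) and
# shared across all instances with that mE; instance differences are purely
# postsynaptic.
selectionInputs <- function(mE, anPars, seed, nTrials, silenceDuration,
                            lowFreq, highFreq, level, dt = 0.01) {
  make <- function(stim, stimIdx, nt) {
    fibers <- generateANTrains(stim, anPars, nFibers = mE, nTrials = nt,
                               seed = seed, stream = stimIdx * 1000 + mE,
                               dt = dt)
    nSteps <- stepsRoundHalfUp(stim@duration, dt)
    c(poolFiberSteps(fibers, dt, nSteps),
      list(nTrials = nt, duration = stim@duration, fibers = fibers))
  }
  list(
    silence = make(silenceStimulus(silenceDuration), 1L, 1L),
    low = make(toneStimulus(lowFreq, level), 2L, nTrials),
    high = make(toneStimulus(highFreq, level), 3L, nTrials))
}

# Run the full selection battery for one parameter set on cached inputs.
evaluateOnInputs <- function(params, inputs, dt = 0.01) {
  run <- function(inp) {
    cfg <- SimulationConfig(dt = dt, duration = inp$duration)
    simulateGBCPooled(inp$steps, inp$offsets, inp$nTrials, params, cfg,
                      meta = list())
  }
  silence <- run(inputs$silence)
  low <- run(inputs$low)
  high <- run(inputs$high)
  sr <- nSpikes(silence) /
    (nTrials(silence) * trialDuration(silence) / 1000)
  mLow <- responseMetrics(low, f = 350)
  mHigh <- responseMetrics(high, f = 7000)
  psth <- computePSTH(high)
  feats <- extractPSTHFeatures(psth)
  pf <- checkPSTHCriteria(feats)
  cls <- classifyInstance(sr, mHigh$dr, mHigh$cvPrime, mLow$vs, mLow$ei, pf)
  list(sr = sr, dr = mHigh$dr, cvp = mHigh$cvPrime, vs = mLow$vs,
       ei = mLow$ei, features = feats, psthFlags = pf,
       category = cls$category, flags = cls$flags)
}

#' Evaluate the full selection battery for one parameter set
#'
#' Generates surrogate AN inputs (silence, low-frequency and high-frequency
#' tones), simulates the instance, computes all selection metrics and
#' classifies it. Works for arbitrary (including off-grid) parameter
#' vectors; used by the grid screen and the convexity analysis.
#'
#' @param params a \code{GBCParameters}.
#' @param anPars an \code{ANSurrogateParameters}.
#' @param seed master seed.
#' @param nTrials trials per tone stimulus.
#' @param silenceDuration continuous silence duration for the spontaneous
#'   rate (ms); 1e5 (100 s) for full runs, 1e4 for the desk preset.
#' @param lowFreq,highFreq,level selection stimuli (Hz, Hz, dB SPL).
#' @return list with sr, dr, cvp, vs, ei, PSTH features and flags, and the
#'   category.
#' @export
evaluateInstance <- function(params, anPars = ANSurrogateParameters(),
                             seed = 1, nTrials = 100,
                             silenceDuration = 1e4, lowFreq = 350,
                             highFreq = 7000, level = 70) {
  inputs <- selectionInputs(params@mE, anPars, seed, nTrials,
                            silenceDuration, lowFreq, highFreq, level)
  evaluateOnInputs(params, inputs)
}

#' Screen a parameter grid against the GBC selection criteria
#'
#' Runs the selection battery (silence; 350 Hz and 7000 Hz tone bursts at
#' 70 dB SPL, 25 ms, 3.9 ms ramps) over every instance of the grid and
#' classifies each one. AN inputs are generated once per (mE, stimulus,
#' seed) and shared across instances with equal mE. Deterministic given the
#' seed. Supports chunked, restartable execution through a checkpoint file.
#'
#' @param grid a \code{ParameterGrid}.
#' @param anPars an \code{ANSurrogateParameters}.
#' @param seed master seed.
#' @param nTrials trials per tone stimulus (1000 for full runs, 100 for the
#'   desk preset).
#' @param silenceDuration silence duration per instance (ms).
#' @param lowFreq,highFreq,level selection stimuli.
#' @param checkpoint optional CSV path; completed rows are appended per
#'   chunk and an interrupted run resumes from it.
#' @param chunkSize instances per checkpoint chunk.
#' @param verbose print per-chunk progress.
#' @return the population table: a data.frame with one row per instance
#'   (id, the six parameters, sr, dr, cvp, vs, ei, P1-P4, category).
#' @export
runSelection <- function(grid, anPars = ANSurrogateParameters(), seed = 1,
                         nTrials = 100, silenceDuration = 1e4,
                         lowFreq = 350, highFreq = 7000, level = 70,
                         checkpoint = NULL, chunkSize = 200,
                         verbose = FALSE) {
  nTotal <- gridSize(grid)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
    if (verbose) message(sprintf("resuming: %d rows done", nrow(done)))
  }
  doneIds <- if (is.null(done)) integer(0) else done$id
  todo <- setdiff(seq_len(nTotal), doneIds)
  if (!length(todo)) return(done[order(done$id), , drop = FALSE])

  idxAll <- instanceIndices(grid, todo)
  mEsTodo <- gridValues(grid)$mE[idxAll[, "mE"]]
  rows <- vector("list", length(todo))
  k <- 0L
  pending <- list()
  flush <- function(pending) {
    if (!is.null(checkpoint) && length(pending)) {
      df <- do.call(rbind, pending)
      utils::write.table(df, checkpoint, sep = ",", row.names = FALSE,
                         col.names = !file.exists(checkpoint), append =
                         file.exists(checkpoint))
    }
  }
  for (mE in sort(unique(mEsTodo))) {
    inputs <- selectionInputs(mE, anPars, seed, nTrials, silenceDuration,
                              lowFreq, highFreq, level)
    inputs$silence$fibers <- inputs$low$fibers <- inputs$high$fibers <- NULL
    ids <- todo[mEsTodo == mE]
    for (i in seq_along(ids)) {
      id <- ids[i]
      params <- instanceParameters(grid, id)
      r <- evaluateOnInputs(params, inputs)
      pv <- parameterVector(params)
      row <- data.frame(id = id, mE = pv[["mE"]], wE = pv[["wE"]],
                        aE = pv[["aE"]], tR = pv[["tR"]], tA = pv[["tA"]],
                        sA = pv[["sA"]], sr = r$sr, dr = r$dr, cvp = r$cvp,
                        vs = r$vs, ei = r$ei,
                        P1 = r$psthFlags[["P1"]], P2 = r$psthFlags[["P2"]],
                        P3 = r$psthFlags[["P3"]], P4 = r$psthFlags[["P4"]],
                        category = r$category, stringsAsFactors = FALSE)
      k <- k + 1L
      rows[[k]] <- row
      pending[[length(pending) + 1L]] <- row
      if (length(pending) >= chunkSize) {
        flush(pending); pending <- list()
        if (verbose) message(sprintf("done %d / %d", k, length(todo)))
      }
    }
  }
  flush(pending)
  tab <- do.call(rbind, rows[seq_len(k)])
  if (!is.null(done)) tab <- rbind(done, tab)
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# ---- dimensional stacking ---------------------------------------------

#' Dimensional stack of a population table
#'
#' Nests the six grid dimensions into three layers of two-dimensional
#' spaces and returns one value per instance as a single 2-D matrix. The
#' layout gives three (row, column) dimension pairs from outer to inner:
#' each cell of the outer layer contains the full middle layer, and each
#' middle cell the full inner layer. The reference layout pairs
#' (mE, sA), (aE, tR), (wE, tA), giving a 630 x 900 matrix on the full
#' grid.
#'
#' @param table population table from [runSelection()] (must cover each
#'   included instance exactly once).
#' @param layout list of three character pairs, e.g.
#'   \code{list(c("mE","sA"), c("aE","tR"), c("wE","tA"))}; all six
#'   dimensions exactly once.
#' @param value name of the table column to display.
#' @param grid the \code{ParameterGrid} the table was computed on.
#' @return numeric matrix of dimension
#'   (n1*n3*n5) x (n2*n4*n6) for the layout dimension counts, with
#'   attributes \code{rowDims} and \code{colDims} describing the nesting;
#'   cells of instances absent from the table are NA.
#' @export
dimensionalStack <- function(table, layout = list(c("mE", "sA"),
                                                  c("aE", "tR"),
                                                  c("wE", "tA")),
                             value = "dr", grid = buildGrid()) {
  dims <- unlist(layout)
  if (length(layout) != 3L || !setequal(dims, GRID_DIMS) ||
      length(dims) != 6L)
    stop("layout must name all six dimensions exactly once as three pairs")
  if (!value %in% names(table)) stop("unknown value column: ", value)
  if (anyDuplicated(table$id)) stop("table has duplicate instance ids")
  rowDims <- vapply(layout, `[`, character(1), 1)
  colDims <- vapply(layout, `[`, character(1), 2)
  n <- vapply(gridValues(grid), length, integer(1))
  idx <- instanceIndices(grid, table$id)
  rowIdx <- ((idx[, rowDims[1]] - 1) * n[rowDims[2]] +
             (idx[, rowDims[2]] - 1)) * n[rowDims[3]] + idx[, rowDims[3]]
  colIdx <- ((idx[, colDims[1]] - 1) * n[colDims[2]] +
             (idx[, colDims[2]] - 1)) * n[colDims[3]] + idx[, colDims[3]]
  m <- matrix(NA_real_, prod(n[rowDims]), prod(n[colDims]))
  m[cbind(rowIdx, colIdx)] <- as.numeric(table[[value]])
  attr(m, "rowDims") <- rowDims
  attr(m, "colDims") <- colDims
  m
}

# ---- frequency response area ------------------------------------------

#' Threshold curve and Q10 from a rate surface
#'
#' Pure analysis step of the frequency response area: for each stimulus
#' frequency, the threshold is the sound level at which the driven rate
#' crosses 10 spikes/s above the spontaneous rate (linear interpolation in
#' dB); Q10 is the characteristic frequency divided by the tuning-curve
#' bandwidth 10 dB above the minimal threshold (interpolated linearly in
#' log-frequency).
#'
#' @param rates matrix of sustained rates (rows = frequencies, columns =
#'   levels), spikes/s.
#' @param freqs stimulus frequencies (Hz), ascending.
#' @param levels sound levels (dB SPL), ascending.
#' @param sr spontaneous rate (spikes/s).
#' @param cf characteristic frequency (Hz); defaults to the frequency of
#'   minimal threshold.
#' @return list with \code{threshold} (per-frequency dB, NA where never
#'   crossed), \code{cf}, \code{minThreshold}, \code{q10} and the 10-dB
#'   bandwidth edges.
#' @export
fraFromRates <- function(rates, freqs, levels, sr, cf = NULL) {
  stopifnot(nrow(rates) == length(freqs), ncol(rates) == length(levels))
  target <- sr + 10
  thr <- rep(NA_real_, length(freqs))
  for (i in seq_along(freqs)) {
    # rate-level functions are monotone in this model; enforce it so
    # sampling noise cannot produce spurious crossings
    r <- cummax(rates[i, ])
    j <- which(r >= target)[1]
    if (is.na(j)) next
    thr[i] <- if (j == 1L) levels[1]
      else levels[j - 1] + (target - r[j - 1]) / (r[j] - r[j - 1]) *
        (levels[j] - levels[j - 1])
  }
  if (all(is.na(thr)))
    return(list(threshold = thr, cf = NA_real_, minThreshold = NA_real_,
                q10 = NA_real_, bandwidth = c(NA_real_, NA_real_)))
  iMin <- which.min(thr)
  minThr <- thr[iMin]
  if (is.null(cf)) cf <- freqs[iMin]
  cut <- minThr + 10
  lf <- log2(freqs)
  crossing <- function(i0, i1) {
    # interpolate the frequency where thr crosses `cut` between i0 and i1
    t0 <- thr[i0]; t1 <- thr[i1]
    2^(lf[i0] + (cut - t0) / (t1 - t0) * (lf[i1] - lf[i0]))
  }
  below <- !is.na(thr) & thr <= cut
  lo <- freqs[which(below)[1]]
  hi <- freqs[rev(which(below))[1]]
  iLo <- which(below)[1]
  if (iLo > 1 && !is.na(thr[iLo - 1])) lo <- crossing(iLo - 1, iLo)
  iHi <- rev(which(below))[1]
  if (iHi < length(freqs) && !is.na(thr[iHi + 1])) hi <- crossing(iHi + 1,
                                                                  iHi)
  list(threshold = thr, cf = cf, minThreshold = minThr,
       q10 = cf / (hi - lo), bandwidth = c(lo, hi))
}

#' Simulate a frequency response area for one instance
#'
#' Drives the instance with tone bursts over a frequency x level grid at a
#' fixed fiber CF, measures sustained rates and applies [fraFromRates()].
#'
#' @param params a \code{GBCParameters}.
#' @param cf fiber characteristic frequency (Hz).
#' @param freqs,levels stimulus grids.
#' @param anPars an \code{ANSurrogateParameters}.
#' @param seed master seed.
#' @param nTrials trials per condition.
#' @param silenceDuration silence duration (ms) for the spontaneous rate.
#' @param toneDuration tone-burst duration (ms); a longer burst gives a
#'   longer sustained window and a less noisy rate estimate per condition.
#' @param window sustained analysis window (ms).
#' @return list with the rate matrix and the [fraFromRates()] results.
#' @export
computeFRA <- function(params, cf, freqs, levels,
                       anPars = ANSurrogateParameters(), seed = 1,
                       nTrials = 20, silenceDuration = 5e3,
                       toneDuration = 25, window = c(10, toneDuration)) {
  sil <- generateANTrains(silenceStimulus(silenceDuration), anPars,
                          nFibers = params@mE, nTrials = 1, seed = seed,
                          stream = 9000L)
  out0 <- simulateGBC(sil, params)
  sr <- nSpikes(out0) / (trialDuration(out0) / 1000)
  rates <- matrix(NA_real_, length(freqs), length(levels))
  for (i in seq_along(freqs)) for (j in seq_along(levels)) {
    stim <- toneStimulus(freqs[i], levels[j], duration = toneDuration,
                         cf = cf)
    fib <- generateANTrains(stim, anPars, nFibers = params@mE,
                            nTrials = nTrials, seed = seed,
                            stream = 9000L + i * 100L + j)
    out <- simulateGBC(fib, params)
    rates[i, j] <- spontAndDrivenRates(out0, out, window = window)[["dr"]]
  }
  c(list(rates = rates, freqs = freqs, levels = levels, sr = sr),
    fraFromRates(rates, freqs, levels, sr, cf = cf))
}

# ---- population validation protocols ----------------------------------

#' Population validation protocols
#'
#' Runs one of the validation batteries over a set of accepted instances
#' and reports population envelopes:
#' \describe{
#'   \item{frequency_sweep}{tone bursts over \code{freqs} at 70 dB SPL (CF
#'     tracking the stimulus); per-frequency min-max envelopes of VS and
#'     EI across instances.}
#'   \item{tail}{500 Hz tone at 95 dB SPL across fiber CFs \code{cfs};
#'     per-CF envelopes of VS at 500 Hz.}
#'   \item{sam}{100 Hz / 100% SAM carrier at each instance's CF over
#'     \code{levels}; per-instance maximum envelope VS over the level
#'     sweep.}
#' }
#'
#' @param paramsList list of \code{GBCParameters} (the accepted set).
#' @param protocol one of "frequency_sweep", "tail", "sam".
#' @param freqs tone frequencies (Hz) for the frequency sweep.
#' @param cfs fiber CFs (Hz) for the tail protocol.
#' @param levels dB SPL levels for the SAM sweep.
#' @param carrier SAM carrier frequency (Hz).
#' @param anPars an \code{ANSurrogateParameters}.
#' @param seed master seed.
#' @param nTrials trials per condition.
#' @param samDuration SAM trial duration (ms).
#' @return a data.frame of conditions with lower/upper envelope columns
#'   (frequency_sweep, tail), or per-instance maximum VS (sam).
#' @export
runValidationProtocols <- function(paramsList,
                                   protocol = c("frequency_sweep", "tail",
                                                "sam"),
                                   freqs = c(200, 350, 500, 1000, 2000,
                                             3500, 5000),
                                   cfs = c(1000, 2000, 3500, 7000, 10000),
                                   levels = seq(10, 45, by = 5),
                                   carrier = 7000,
                                   anPars = ANSurrogateParameters(),
                                   seed = 1, nTrials = 50,
                                   samDuration = 600) {
  protocol <- match.arg(protocol)
  if (!length(paramsList)) stop("empty accepted set")
  vsei <- function(params, stim, f, stream, window) {
    fib <- generateANTrains(stim, anPars, nFibers = params@mE,
                            nTrials = nTrials, seed = seed, stream = stream)
    out <- simulateGBC(fib, params)
    sust <- sustainedWindow(out, window[1], window[2])
    c(vs = vectorStrength(sust, f), ei = entrainmentIndex(sust, f))
  }
  if (protocol == "frequency_sweep") {
    res <- lapply(seq_along(freqs), function(i) {
      m <- vapply(paramsList, vsei, numeric(2),
                  stim = toneStimulus(freqs[i], 70), f = freqs[i],
                  stream = 100L + i, window = c(10, 25))
      data.frame(frequency = freqs[i],
                 vsLower = min(m["vs", ]), vsUpper = max(m["vs", ]),
                 eiLower = min(m["ei", ]), eiUpper = max(m["ei", ]))
    })
    return(do.call(rbind, res))
  }
  if (protocol == "tail") {
    res <- lapply(seq_along(cfs), function(i) {
      m <- vapply(paramsList, vsei, numeric(2),
                  stim = toneStimulus(500, 95, cf = cfs[i]), f = 500,
                  stream = 200L + i, window = c(10, 25))
      data.frame(cf = cfs[i], vsLower = min(m["vs", ]),
                 vsUpper = max(m["vs", ]))
    })
    return(do.call(rbind, res))
  }
  # sam: per instance, maximum envelope VS over the level sweep
  res <- lapply(seq_along(paramsList), function(k) {
    vsl <- vapply(seq_along(levels), function(j) {
      stim <- samStimulus(carrier, levels[j], duration = samDuration)
      vsei(paramsList[[k]], stim, f = stim@modFrequency,
           stream = 300L + k * 50L + j,
           window = c(10, samDuration))[["vs"]]
    }, numeric(1))
    data.frame(instance = k, maxVS = max(vsl),
               bestLevel = levels[which.max(vsl)])
  })
  do.call(rbind, res)
}
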