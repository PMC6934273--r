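# Spike-time files, configuration JSON and result tables.

#' Write spike trains to a delimited spike-time file
#'
#' Tab-separated text with header columns \code{trial}, \code{fiber},
#' \code{time_ms}. Times are written at 0.01 ms resolution and round-trip
#' exactly through [readSpikeFile()] / [loadANTrains()].
#'
#' @param trains a \code{SpikeTrains} or list of them (one per fiber).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSpikeFile <- function(trains, path) {
  if (is(trains, "SpikeTrains")) trains <- list(trains)
  rows <- list()
  for (f in seq_along(trains)) {
    st <- trains[[f]]
    for (tr in seq_len(nTrials(st))) {
      tt <- st@trials[[tr]]
      if (length(tt))
        rows[[length(rows) + 1L]] <-
          data.frame(trial = tr, fiber = f,
                     time_ms = sprintf("%.2f", tt))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(trial = integer(0), fiber = integer(0),
                        time_ms = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a delimited spike-time file
#'
#' @param path file with header columns \code{trial}, \code{fiber},
#'   \code{time_ms} (tab/comma/whitespace separated). Malformed rows and
#'   unsorted within-trial times raise an error naming the line.
#' @return data.frame with columns trial, fiber, time_ms.
#' @export
readSpikeFile <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed spike file: ", conditionMessage(e)))
  need <- c("trial", "fiber", "time_ms")
  if (!all(need %in% names(df)))
    stop("spike file must have columns trial, fiber, time_ms")
  df <- df[, need]
  for (j in need) df[[j]] <- as.numeric(df[[j]])
  bad <- which(!is.finite(df$trial) | !is.finite(df$fiber) |
                 !is.finite(df$time_ms) | df$time_ms < 0)
  if (length(bad))
    stop(sprintf("malformed spike row at data line %d", bad[1]))
  # within (fiber, trial), times must be sorted
  o <- order(df$fiber, df$trial)
  ds <- df[o, ]
  grp <- paste(ds$fiber, ds$trial)
  sameGrp <- grp[-1] == grp[-length(grp)]
  if (nrow(df) > 1) {
    nonInc <- which(sameGrp & diff(ds$time_ms) <= 0)
    if (length(nonInc))
      stop(sprintf("unsorted spike times at data line %d",
                   o[nonInc[1] + 1]))
  }
  df
}

#' Read a JSON run configuration
#'
#' Validates the recognized blocks of a run configuration: \code{grid}
#' (per-dimension value overrides), \code{an_surrogate} (surrogate
#' parameter overrides), \code{seed}, \code{trials},
#' \code{silence_duration_ms} and \code{preset} ("desk" or "full"). An
#' unknown field raises an error naming the field.
#'
#' @param path JSON file path.
#' @return validated configuration list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("grid", "an_surrogate", "seed", "trials",
             "silence_duration_ms", "preset")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field: ", bad[1])
  preset <- if (is.null(cfg$preset)) "desk" else cfg$preset
  if (!preset %in% c("desk", "full"))
    stop("unknown config field: preset value '", preset, "'")
  out <- list(
    grid = if (preset == "desk") deskGrid() else buildGrid(),
    anPars = ANSurrogateParameters(),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    trials = if (is.null(cfg$trials)) {
      if (preset == "desk") 100L else 1000L
    } else as.integer(cfg$trials),
    silenceDuration = if (is.null(cfg$silence_duration_ms)) {
      if (preset == "desk") 1e4 else 1e5
    } else as.numeric(cfg$silence_duration_ms),
    preset = preset)
  if (!is.null(cfg$grid)) out$grid <- buildGrid(as.list(cfg$grid))
  if (!is.null(cfg$an_surrogate)) {
    ov <- as.list(cfg$an_surrogate)
    valid <- slotNames("ANSurrogateParameters")
    bad <- setdiff(names(ov), valid)
    if (length(bad)) stop("unknown config field: an_surrogate.", bad[1])
    out$anPars <- do.call(ANSurrogateParameters, ov)
  }
  out
}

#' Write a result table as CSV with fixed precision
#'
#' Numeric columns are formatted with 6 significant digits so repeated runs
#' are byte-identical.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResultCSV <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a histogram as two-column CSV
#'
#' @param h a \code{SpikeHistogram}.
#' @param path output path.
#' @param what "counts" or "rate" (smoothed rate; PSTH only).
#' @return the path, invisibly.
#' @export
writeHistogramCSV <- function(h, path, what = c("counts", "rate")) {
  what <- match.arg(what)
  value <- if (what == "rate") smoothedRate(h) else histCounts(h)
  writeResultCSV(data.frame(bin_center = binCenters(h), value = value),
                 path)
}
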