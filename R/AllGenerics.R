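# Accessor generics for the S4 domain classes. Slot access from user code
# should go through these.

#' Number of trials
#' @param x a \code{SpikeTrains} object.
#' @return integer(1)
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname nTrials
#' @export
setMethod("nTrials", "SpikeTrains", function(x) length(x@trials))

#' Trial duration in ms
#' @param x a \code{SpikeTrains} object.
#' @return numeric(1), ms
#' @export
setGeneric("trialDuration", function(x) standardGeneric("trialDuration"))

#' @rdname trialDuration
#' @export
setMethod("trialDuration", "SpikeTrains", function(x) x@trialDuration)

#' Per-trial spike times
#' @param x a \code{SpikeTrains} object.
#' @return list of numeric vectors (ms)
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "SpikeTrains", function(x) x@trials)

#' Total spike count
#' @param x a \code{SpikeTrains} object.
#' @return integer(1)
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "SpikeTrains",
          function(x) sum(vapply(x@trials, length, integer(1))))

#' Model parameters as a named list or vector
#' @param x a \code{GBCParameters} object.
#' @return named numeric vector with elements mE, wE, aE, tR, tA, sA
#' @export
setGeneric("parameterVector", function(x) standardGeneric("parameterVector"))

#' @rdname parameterVector
#' @export
setMethod("parameterVector", "GBCParameters", function(x)
  c(mE = as.numeric(x@mE), wE = x@wE, aE = x@aE, tR = x@tR, tA = x@tA,
    sA = x@sA))

#' Grid dimension value lists
#' @param x a \code{ParameterGrid}.
#' @return named list of six numeric vectors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "ParameterGrid", function(x) x@values)

#' Number of instances in a grid
#' @param x a \code{ParameterGrid}.
#' @return numeric(1)
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname gridSize
#' @export
setMethod("gridSize", "ParameterGrid",
          function(x) prod(vapply(x@values, length, integer(1))))

#' Histogram bin centers
#' @param x a \code{SpikeHistogram}.
#' @return numeric vector of bin midpoints
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binCenters
#' @export
setMethod("binCenters", "SpikeHistogram", function(x)
  (x@binEdges[-length(x@binEdges)] + x@binEdges[-1]) / 2)

#' Histogram counts
#' @param x a \code{SpikeHistogram}.
#' @return numeric vector of per-bin counts
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))

#' @rdname histCounts
#' @export
setMethod("histCounts", "SpikeHistogram", function(x) x@counts)

#' Smoothed PSTH rate (spikes/s)
#' @param x a \code{SpikeHistogram} of kind "psth".
#' @return numeric vector, spikes/s per bin
#' @export
setGeneric("smoothedRate", function(x) standardGeneric("smoothedRate"))

#' @rdname smoothedRate
#' @export
setMethod("smoothedRate", "SpikeHistogram", function(x) x@smoothedRate)
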