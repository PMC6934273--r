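#' One exact digital update of the dynamic threshold
#'
#' The dynamic threshold component follows the first-order relaxation
#' \eqn{T_A \, d\theta_D/dt = -\theta_D + S_A v(t)} toward \eqn{S_A v}. With
#' the summed input count \eqn{v} constant over a time step (guaranteed by
#' the rectangular input shape), the update has the exact solution
#' \deqn{\theta_D(t + \Delta t) = e^{-\Delta t/T_A}\,\theta_D(t) +
#'   (1 - e^{-\Delta t/T_A})\, S_A\, v(t),}
#' which this function evaluates; no ODE discretization error is incurred.
#'
#' @param thetaD current dynamic threshold (dimensionless, >= 0).
#' @param v summed input count at the current step (dimensionless, >= 0).
#' @param tA adaptation time constant (ms, > 0).
#' @param sA adaptation strength (dimensionless, >= 0).
#' @param dt time step (ms, > 0).
#' @return the dynamic threshold after one step.
#' @examples
#' updateThreshold(0, 1, tA = 0.25, sA = 0.8, dt = 0.01)
#' @export
updateThreshold <- function(thetaD, v, tA, sA, dt) {
  if (!is.finite(tA) || tA <= 0) stop("tA must be a positive finite number")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive finite number")
  stopifnot(is.finite(thetaD), thetaD >= 0, is.finite(v), v >= 0, sA >= 0)
  a <- exp(-dt / tA)
  a * thetaD + (1 - a) * sA * v
}

#' Simulate the adaptive coincidence counting GBC model
#'
#' Drives the model with a set of auditory-nerve input fiber trains on a
#' fixed time grid. At each step the summed input count \eqn{v(t)} is
#' \code{aE} times the number of input spikes whose rectangular count (of
#' duration \code{wE}, half-open window) covers the step. An output spike is
#' emitted when the model is not refractory and \eqn{v \ge \theta_S +
#' \theta_D} (static threshold \eqn{\theta_S = 1}); after a spike no output
#' is produced for \code{tR} ms. The dynamic threshold is updated at every
#' step from the input history alone: it is neither reset by output spikes
#' nor frozen during refractoriness. Within a step, the threshold is
#' compared before \eqn{\theta_D} absorbs that step's input. Input spike
#' times are snapped to the grid and \code{wE}, \code{tR} are quantized by
#' round-half-up (the window to at least one step).
#'
#' @param inputs list of \code{SpikeTrains}, one per input fiber (all with
#'   the same trial count and duration), or a single \code{SpikeTrains}
#'   whose trials hold the pooled input of all fibers per trial.
#' @param params a \code{GBCParameters} object.
#' @param config a \code{SimulationConfig}; its duration defaults to the
#'   input trial duration.
#' @return a \code{SpikeTrains} with the output spike times per trial.
#' @examples
#' volley <- lapply(1:3, function(i)
#'   SpikeTrains(list(c(1.0)), trialDuration = 5))
#' out <- simulateGBC(volley, GBCParameters())
#' spikeTimes(out)
#' @export
simulateGBC <- function(inputs, params, config = NULL) {
  validObject(params)
  if (is(inputs, "SpikeTrains")) inputs <- list(inputs)
  if (!length(inputs) || !all(vapply(inputs, is, logical(1), "SpikeTrains")))
    stop("inputs must be a list of SpikeTrains (one per fiber)")
  nt <- unique(vapply(inputs, nTrials, integer(1)))
  du <- unique(vapply(inputs, trialDuration, numeric(1)))
  if (length(nt) != 1L || length(du) != 1L)
    stop("all input fibers must share the same trial count and duration")
  if (length(inputs) != 1L && length(inputs) != params@mE)
    stop(sprintf("expected %d input fibers, got %d", params@mE,
                 length(inputs)))
  if (is.null(config)) config <- SimulationConfig(duration = du)
  validObject(config)
  dt <- config@dt
  nSteps <- stepsRoundHalfUp(config@duration, dt)
  pooled <- poolFiberSteps(inputs, dt, nSteps)
  simulateGBCPooled(pooled$steps, pooled$offsets, nt, params, config,
                    meta = list(source = "simulateGBC"))
}

# Pool fiber trains into sorted snapped step indices per trial, with 0-based
# offsets (length nTrials + 1). Shared across instances with equal mE.
poolFiberSteps <- function(inputs, dt, nSteps) {
  nt <- nTrials(inputs[[1]])
  steps <- vector("list", nt)
  for (tr in seq_len(nt)) {
    tt <- unlist(lapply(inputs, function(f) f@trials[[tr]]), use.names = FALSE)
    s <- snapToStep(tt, dt)
    s <- s[s >= 0 & s < nSteps]
    steps[[tr]] <- sort.int(s)
  }
  lens <- vapply(steps, length, integer(1))
  list(steps = as.integer(unlist(steps, use.names = FALSE)),
       offsets = as.integer(c(0, cumsum(lens))))
}

# Core batched run on pre-pooled step indices.
simulateGBCPooled <- function(steps, offsets, nt, params, config, meta) {
  dt <- config@dt
  nSteps <- stepsRoundHalfUp(config@duration, dt)
  winSteps <- max(1L, stepsRoundHalfUp(params@wE, dt))
  refSteps <- stepsRoundHalfUp(params@tR, dt)
  alpha <- exp(-dt / params@tA)
  res <- .ccSimulateBatch(steps, offsets, nSteps, winSteps, refSteps,
                          params@aE, params@sA, alpha, config@initialThetaD)
  trials <- vector("list", nt)
  for (tr in seq_len(nt)) trials[[tr]] <- numeric(0)
  if (length(res$step)) {
    times <- res$step * dt
    byTrial <- split(times, factor(res$trial, levels = seq_len(nt)))
    trials <- lapply(byTrial, as.numeric)
  }
  new("SpikeTrains", trials = trials, trialDuration = config@duration,
      meta = c(meta, list(params = parameterVector(params), dt = dt)))
}
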