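# Internal helpers: grid quantization and deterministic child seeds.

# Round-half-up to an integer number of dt steps.
stepsRoundHalfUp <- function(x, dt) as.integer(floor(x / dt + 0.5))

# Quantize a time onto the dt grid (index of the nearest step, 0-based).
snapToStep <- function(t, dt) as.integer(floor(t / dt + 0.5))

MINSTD_M <- 2147483647
MINSTD_A <- 48271

minstd <- function(x) {
  x <- x %% MINSTD_M
  if (x == 0) x <- 1
  (MINSTD_A * x) %% MINSTD_M
}

#' Deterministic child seed derivation
#'
#' Spawns reproducible per-fiber, per-trial seeds from one master seed so
#' that any single fiber/trial is reproducible in isolation. The master seed
#' and a stream id are mixed through two rounds of the minimal-standard
#' Lehmer generator (a bijection on its modulus ring), then the cell index
#' \code{fiber * maxTrials + trial} is added before two further rounds, which
#' makes the map injective over cells of one stream.
#'
#' @param master master seed (integer).
#' @param fiber fiber index (1-based).
#' @param trial trial index (1-based).
#' @param stream stream id separating stimuli/protocol stages (integer).
#' @param maxTrials cell stride; must exceed any trial index used.
#' @return integer seed in [1, 2^31 - 2], suitable for \code{set.seed}.
#' @export
childSeed <- function(master, fiber = 1L, trial = 1L, stream = 0L,
                      maxTrials = 100000L) {
  s0 <- minstd(minstd(abs(master) + 1 + stream * 7919))
  cell <- (s0 + (fiber - 1) * maxTrials + (trial - 1)) %% MINSTD_M
  as.integer(minstd(minstd(cell)))
}
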