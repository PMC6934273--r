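# Grid construction, id bijection, the selection screen, dimensional
# stacking, FRA analysis and population envelopes.

test_that("the default grid enumerates 7x10x9x9x10x10 instances", {
  g <- buildGrid()
  expect_equal(gridSize(g), 567000)
  expect_equal(unname(vapply(gridValues(g), length, integer(1))),
               c(7, 10, 9, 9, 10, 10))
  # the reference instance lies on the grid
  def <- parameterVector(defaultParameters())
  v <- gridValues(g)
  for (d in names(def)) expect_true(def[[d]] %in% v[[d]])
})

test_that("grid overrides and degenerate grids behave", {
  expect_equal(gridSize(buildGrid(lapply(
    stats::setNames(gbcpop:::GRID_DIMS, gbcpop:::GRID_DIMS),
    function(d) c(1, 2)))), 64)
  one <- buildGrid(list(mE = 20, wE = 0.32, aE = 0.4, tR = 1.2, tA = 0.25,
                        sA = 0.8))
  expect_equal(gridSize(one), 1)
  expect_error(buildGrid(list(mE = numeric(0))), "empty")
  expect_error(buildGrid(list(bogus = 1)), "unknown")
})

test_that("instance ids and grid indices are a bijection", {
  g <- deskGrid()
  n <- gridSize(g)
  expect_equal(n, 729)
  ids <- seq_len(n)
  idx <- instanceIndices(g, ids)
  expect_equal(instanceId(g, idx), as.numeric(ids))
  # spot-check the full grid
  gf <- buildGrid()
  some <- c(1, 567000, 12345, 300001)
  expect_equal(instanceId(gf, instanceIndices(gf, some)), some)
  p <- instanceParameters(gf, 1)
  expect_equal(unname(parameterVector(p)),
               unname(vapply(gridValues(gf), `[`, numeric(1), 1)))
})

test_that("a one-instance selection run is deterministic and classifiable", {
  one <- buildGrid(list(mE = 20, wE = 0.32, aE = 0.4, tR = 1.2, tA = 0.25,
                        sA = 0.8))
  a <- runSelection(one, seed = 5, nTrials = 60, silenceDuration = 4000)
  b <- runSelection(one, seed = 5, nTrials = 60, silenceDuration = 4000)
  expect_identical(a, b)
  expect_equal(nrow(a), 1)
  expect_equal(a$category, "PLN")
  # matches the uncached single-instance evaluator (input caching is
  # transparent)
  r <- evaluateInstance(instanceParameters(one, 1), seed = 5, nTrials = 60,
                        silenceDuration = 4000)
  expect_equal(a$vs, r$vs)
  expect_equal(a$dr, r$dr)
  expect_equal(a$sr, r$sr)
})

test_that("a grid that cannot reach threshold is rejected wholesale", {
  weak <- buildGrid(list(mE = 3, wE = 0.32, aE = c(0.05, 0.1), tR = 1.2,
                         tA = 0.25, sA = 0.8))   # mE*aE < 1
  tab <- runSelection(weak, seed = 1, nTrials = 20, silenceDuration = 2000)
  expect_true(all(tab$category == "REJECTED_RATES"))
  expect_true(all(tab$dr == 0))
})

test_that("an interrupted screen resumes from its checkpoint", {
  g <- buildGrid(list(mE = c(12, 20), wE = 0.32, aE = c(0.3, 0.4), tR = 1.2,
                      tA = 0.25, sA = 0.8))
  full <- runSelection(g, seed = 5, nTrials = 20, silenceDuration = 2000)
  ck <- withr::local_tempfile(fileext = ".csv")
  partial <- runSelection(buildGrid(list(mE = c(12, 20), wE = 0.32,
                                         aE = c(0.3, 0.4), tR = 1.2,
                                         tA = 0.25, sA = 0.8)),
                          seed = 5, nTrials = 20, silenceDuration = 2000,
                          checkpoint = ck, chunkSize = 1)
  done <- utils::read.csv(ck)
  utils::write.csv(done[1:2, ], ck, row.names = FALSE)  # drop half
  resumed <- runSelection(g, seed = 5, nTrials = 20,
                          silenceDuration = 2000, checkpoint = ck)
  expect_equal(resumed$category, full$category)
  expect_equal(resumed$vs, full$vs)
})

test_that("dimensional stacking is a bijection onto the matrix", {
  vals <- lapply(stats::setNames(gbcpop:::GRID_DIMS, gbcpop:::GRID_DIMS),
                 function(d) c(1, 2))
  g <- buildGrid(vals)
  tab <- data.frame(id = 1:64)
  idx <- instanceIndices(g, tab$id)
  for (d in gbcpop:::GRID_DIMS) tab[[d]] <- gridValues(g)[[d]][idx[, d]]
  tab$value <- tab$id
  m <- dimensionalStack(tab, value = "value", grid = g)
  expect_equal(dim(m), c(8, 8))
  expect_equal(sort(as.vector(m)), as.numeric(1:64))
  expect_error(dimensionalStack(tab, layout = list(c("mE", "sA"),
                                                   c("aE", "tR")),
                                value = "value", grid = g), "layout")
})

test_that("the reference layout stacks the full grid into 630 x 900", {
  gf <- buildGrid()
  tab <- data.frame(id = seq_len(567000), value = seq_len(567000))
  m <- dimensionalStack(tab, value = "value", grid = gf)
  expect_equal(dim(m), c(7 * 9 * 10, 10 * 9 * 10))
  expect_false(anyNA(m))
  expect_equal(attr(m, "rowDims"), c("mE", "aE", "wE"))
})

test_that("FRA thresholds recover a rectangular response region", {
  freqs <- c(1000, 2000, 4000, 8000)
  levels <- seq(0, 80, by = 10)
  rates <- matrix(0, 4, 9)
  rates[2:3, levels >= 40] <- 100   # response only above 40 dB, mid freqs
  fra <- fraFromRates(rates, freqs, levels, sr = 10)
  expect_true(all(is.na(fra$threshold[c(1, 4)])))
  # crossing of SR+10 = 20 interpolated between 30 dB (rate 0) and 40 dB
  # (rate 100): 32 dB
  expect_equal(fra$threshold[2:3], c(32, 32))
  flat <- fraFromRates(matrix(10, 4, 9), freqs, levels, sr = 10)
  expect_true(all(is.na(flat$threshold)))
})

test_that("Q10 equals cf over the 10 dB bandwidth of a V-shaped tuning", {
  cf <- 4000
  freqs <- 2^seq(log2(1000), log2(16000), length.out = 81)
  levels <- seq(-10, 100, by = 1)
  thr <- 20 + 40 * abs(log2(freqs / cf))    # V with 40 dB/oct flanks
  rates <- outer(seq_along(freqs), seq_along(levels), function(i, j)
    ifelse(levels[j] >= thr[i], 100, 0))
  fra <- fraFromRates(rates, freqs, levels, sr = 10, cf = cf)
  bw <- cf * (2^(10 / 40) - 2^(-10 / 40))   # analytic 10 dB bandwidth
  expect_equal(fra$q10, cf / bw, tolerance = 0.05)
})

test_that("population envelopes collapse for one instance and widen with more", {
  p1 <- defaultParameters()
  p2 <- GBCParameters(mE = 25, sA = 1.0)
  one <- runValidationProtocols(list(p1), "frequency_sweep", freqs = 350,
                                nTrials = 30, seed = 2)
  expect_equal(one$vsLower, one$vsUpper)
  both <- runValidationProtocols(list(p1, p2), "frequency_sweep",
                                 freqs = 350, nTrials = 30, seed = 2)
  expect_lte(both$vsLower, one$vsLower)
  expect_gte(both$vsUpper, one$vsUpper)
})
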