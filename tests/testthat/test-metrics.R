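# Output measures: windowing, VS, EI, CV', PSTH and histograms.

test_that("sustained window is half-open on [start, end)", {
  st <- train1(c(5, 12, 24.9, 25), duration = 25)
  expect_equal(spikeTimes(sustainedWindow(st))[[1]], c(12, 24.9))
  expect_length(spikeTimes(sustainedWindow(train1(numeric(0))))[[1]], 0)
  allIn <- train1(c(11, 15, 20))
  expect_equal(spikeTimes(sustainedWindow(allIn))[[1]], c(11, 15, 20))
})

test_that("vector strength has its analytic values on constructed phase sets", {
  f <- 500; Tms <- 1000 / f
  same <- train1(10 + Tms * (0:9))                       # all at one phase
  expect_equal(vectorStrength(same, f), 1)
  quad <- train1(10 + Tms * c(0, 0.25, 0.5, 0.75))       # symmetric
  expect_equal(vectorStrength(quad, f), 0, tolerance = 1e-12)
  two <- train1(10 + Tms * c(0, 0.25))                   # |(1+i)/2|
  expect_equal(vectorStrength(two, f), sqrt(2) / 2)
  expect_true(is.na(vectorStrength(train1(numeric(0)), f)))
})

test_that("entrainment index counts ISIs within half a period of 1/f", {
  f <- 500; Tms <- 1000 / f
  expect_equal(entrainmentIndex(periodicTrain(Tms, 10), f), 1)
  expect_equal(entrainmentIndex(periodicTrain(2 * Tms, 10, duration = 60),
                                f), 0)
  mixed <- train1(cumsum(c(1, Tms, 2 * Tms, Tms)), duration = 25)
  expect_equal(entrainmentIndex(mixed, f), 2 / 3)
  expect_true(is.na(entrainmentIndex(train1(c(1)), f)))
})

test_that("EI never straddles trial boundaries", {
  f <- 500
  st <- SpikeTrains(list(c(1, 3), c(1, 3)), trialDuration = 25)
  # only the two within-trial ISIs (2 ms = period) count
  expect_equal(entrainmentIndex(st, f), 1)
})

test_that("CV' uses the population SD and the dead-time correction", {
  expect_equal(cvPrime(periodicTrain(2, 10)), 0)
  st <- train1(cumsum(c(1, 1.5, 2.5)), duration = 25)   # ISIs 1.5, 2.5
  expect_equal(cvPrime(st, mu0 = 0.5), (0.5) / (2 - 0.5))
  short <- train1(cumsum(c(1, 0.4, 0.4)), duration = 25) # mu = 0.4 < mu0
  expect_true(is.na(cvPrime(short, mu0 = 0.5)))
  expect_true(is.na(cvPrime(train1(c(1, 2)), mu0 = 0.5)))  # only one ISI
})

test_that("CV' is scale-consistent", {
  isis <- c(1.2, 1.9, 2.7, 1.4, 2.2)
  st1 <- train1(1 + cumsum(isis), duration = 25)
  st2 <- train1((1 + cumsum(isis)) * 2 - 1, duration = 25)  # ISIs doubled
  expect_equal(cvPrime(st2, mu0 = 1.0), cvPrime(st1, mu0 = 0.5))
})

test_that("PSTH smoothing spreads single spikes by the triangular kernel", {
  st <- train1(c(12.05), duration = 25)
  h <- computePSTH(st)
  expect_equal(sum(histCounts(h)), 1)
  sm <- smoothedRate(h) * (nTrials(st) * 0.1 / 1000)  # back to counts
  hit <- which(sm > 0)
  expect_length(hit, 5)
  expect_equal(sm[hit], c(1, 2, 3, 2, 1) / 9)
  expect_equal(sum(sm), 1)  # kernel preserves total count
})

test_that("smoothed PSTH rate recovers a constant Poisson rate", {
  rate <- 400; nTr <- 500
  set.seed(12)
  trials <- lapply(seq_len(nTr), function(i)
    sort(runif(rpois(1, rate * 0.025), 0, 25)))
  st <- SpikeTrains(trials, trialDuration = 25)
  h <- computePSTH(st)
  interior <- 10:240
  m <- mean(smoothedRate(h)[interior])
  se <- sqrt(rate / (nTr * 0.025))  # SE of the mean rate estimate
  expect_lt(abs(m - rate), 3 * se)
})

test_that("period and ISI histograms concentrate for periodic trains", {
  f <- 500
  st <- periodicTrain(2, 20)
  ph <- periodHistogram(st, f, nBins = 20)
  expect_equal(sum(histCounts(ph) > 0), 1)
  ih <- isiHistogram(st, bin = 0.1)
  expect_equal(sum(histCounts(ih) > 0), 1)
  expect_equal(binCenters(ih)[which(histCounts(ih) > 0)], 2, tolerance = 0.1)
  # spikes at integer cycles fold to phase zero
  cyc <- train1((0:9) * (1000 / f), duration = 25)
  pc <- periodHistogram(cyc, f, nBins = 10)
  expect_equal(which(histCounts(pc) > 0), 1)
})

test_that("VS and EI are invariant to whole-period time shifts", {
  f <- 400; Tms <- 1000 / f
  set.seed(4)
  tt <- sort(runif(40, 0, 20))
  a <- train1(tt, duration = 100)
  b <- train1(tt + 3 * Tms, duration = 100)
  expect_equal(vectorStrength(a, f), vectorStrength(b, f))
  expect_equal(entrainmentIndex(a, f), entrainmentIndex(b, f))
})

test_that("EI tolerates sub-quarter-period jitter of a periodic train", {
  f <- 500; Tms <- 1000 / f
  set.seed(8)
  base <- 10 + Tms * (0:19)
  # |jitter| < 0.25/f keeps every ISI within (0.5/f, 1.5/f)
  jit <- base + runif(20, -1, 1) * (0.24 * Tms / 2)
  expect_equal(entrainmentIndex(train1(sort(jit), duration = 60), f), 1)
})

test_that("spontaneous and driven rates come out in spikes per second", {
  none <- SpikeTrains(list(numeric(0)), trialDuration = 1000)
  expect_equal(unname(spontAndDrivenRates(none, none)), c(0, 0))
  # one spike per trial inside the 15 ms window -> 66.7 spikes/s
  drv <- SpikeTrains(rep(list(15), 20), trialDuration = 25)
  expect_equal(spontAndDrivenRates(none, drv)[["dr"]], 1 / 0.015)
  sil <- SpikeTrains(list(sort(runif(7000, 0, 1e5))), trialDuration = 1e5)
  expect_equal(spontAndDrivenRates(sil, drv)[["sr"]], 70)
})

test_that("the log(1-VS) display transform is monotone", {
  vs <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(log(1 - vs)) < 0))
})
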