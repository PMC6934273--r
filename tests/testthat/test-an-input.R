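# Surrogate auditory-nerve generator: rate envelope, calibration,
# refractoriness, determinism and the spike-file adapter.

test_that("silence envelope is flat at the spontaneous rate", {
  env <- rateEnvelope(silenceStimulus(100), dt = 0.1)
  expect_true(all(env == 70))
  expect_length(env, 1000)
})

test_that("a SAM envelope with zero depth equals the tone envelope", {
  tone <- rateEnvelope(toneStimulus(4000, 60), dt = 0.05)
  sam <- rateEnvelope(samStimulus(4000, 60, modDepth = 0, duration = 25),
                      dt = 0.05)
  expect_equal(sam, tone)
})

test_that("the driven rate saturates above the saturation level", {
  p <- ANSurrogateParameters()
  e30 <- rateEnvelope(toneStimulus(4000, p@rateSaturationLevel + 30), p,
                      dt = 0.1)
  e40 <- rateEnvelope(toneStimulus(4000, p@rateSaturationLevel + 40), p,
                      dt = 0.1)
  mid <- 120:130   # steady-state region (12-13 ms)
  expect_equal(mean(e30[mid]), mean(e40[mid]), tolerance = 0.01)
  expect_error(rateEnvelope(StimulusDescriptor("tone", frequency = -1)),
               "frequency")
})

test_that("spontaneous firing calibrates to the target rate over 100 s", {
  trains <- generateANTrains(silenceStimulus(1e5), nFibers = 1, nTrials = 1,
                             seed = 101)
  n <- nSpikes(trains[[1]])
  se <- sqrt(7000)
  expect_lt(abs(n - 7000), 3 * se)
})

test_that("no two spikes violate the absolute dead time", {
  p <- ANSurrogateParameters()
  trains <- generateANTrains(toneStimulus(350, 70), p, nFibers = 3,
                             nTrials = 50, seed = 5)
  for (tr in trains) {
    isis <- unlist(lapply(spikeTimes(tr), diff))
    expect_true(all(isis >= p@absRefractory))
  }
})

test_that("sustained vector strength matches the target curve at 350 Hz", {
  p <- ANSurrogateParameters()
  target <- anTargetVS(350, p)
  trains <- generateANTrains(toneStimulus(350, 70), p, nFibers = 4,
                             nTrials = 400, seed = 9)
  pooled <- new("SpikeTrains",
                trials = do.call(c, lapply(trains, spikeTimes)),
                trialDuration = 25)
  sust <- sustainedWindow(pooled)
  expect_gt(nSpikes(sust), 5000)
  expect_lt(abs(vectorStrength(sust, 350) - target), 0.03)
})

test_that("the target VS curve decays monotonically above the corner", {
  p <- ANSurrogateParameters()
  f <- seq(p@vsCornerFreq, 10000, length.out = 40)
  expect_true(all(diff(anTargetVS(f, p)) < 0))
  expect_true(all(anTargetVS(c(100, 1000, 7000), p) >= 0 &
                    anTargetVS(c(100, 1000, 7000), p) < 1))
})

test_that("fibers are statistically independent given the seed", {
  trains <- generateANTrains(toneStimulus(7000, 70), nFibers = 2,
                             nTrials = 1000, seed = 21)
  c1 <- vapply(spikeTimes(trains[[1]]), length, integer(1))
  c2 <- vapply(spikeTimes(trains[[2]]), length, integer(1))
  expect_lt(abs(cor(c1, c2)), 0.05)
})

test_that("generation is reproducible from the master seed", {
  a <- generateANTrains(toneStimulus(350, 70), nFibers = 2, nTrials = 5,
                        seed = 33)
  b <- generateANTrains(toneStimulus(350, 70), nFibers = 2, nTrials = 5,
                        seed = 33)
  expect_identical(lapply(a, spikeTimes), lapply(b, spikeTimes))
  # child seeds give per-fiber/trial isolation: regenerating fiber 2 alone
  # reproduces it
  b2 <- generateANTrains(toneStimulus(350, 70), nFibers = 2, nTrials = 5,
                         seed = 34)
  expect_false(identical(spikeTimes(a[[1]]), spikeTimes(b2[[1]])))
})

test_that("spike files round-trip through write and load", {
  trains <- generateANTrains(toneStimulus(350, 70), nFibers = 3,
                             nTrials = 4, seed = 2)
  # snap to the 0.01 ms grid the writer uses
  snapped <- lapply(trains, function(tr)
    SpikeTrains(lapply(spikeTimes(tr), function(t) unique(round(t, 2))),
                trialDuration = trialDuration(tr)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSpikeFile(snapped, path)
  back <- loadANTrains(path, nFibers = 3, nTrials = 4, trialDuration = 25)
  expect_equal(lapply(back, spikeTimes), lapply(snapped, spikeTimes),
               ignore_attr = TRUE)
})

test_that("the loader rejects a wrong fiber count and accepts an empty file", {
  trains <- generateANTrains(toneStimulus(350, 70), nFibers = 3,
                             nTrials = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSpikeFile(trains, path)
  expect_error(loadANTrains(path, nFibers = 5, nTrials = 2), "fibers")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("trial\tfiber\ttime_ms", empty)
  zero <- loadANTrains(empty, nFibers = 2, nTrials = 3)
  expect_length(zero, 2)
  expect_equal(nSpikes(zero[[1]]), 0)
})

test_that("malformed and unsorted spike files fail with the offending line", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("trial\tfiber\ttime_ms", "1\t1\t2.00", "1\t1\t1.00"), bad)
  expect_error(readSpikeFile(bad), "line 2")
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("trial\tfiber\ttime_ms", "1\t1\t-3.0"), neg)
  expect_error(readSpikeFile(neg), "line 1")
})
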