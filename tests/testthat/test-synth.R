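test_that("simulated spectra follow the closed-form spectral model", {
  f <- 3:50
  expect_equal(simulatePowerSpectrum(c(0, 0), list(), f), rep(0, length(f)))
  expect_equal(simulatePowerSpectrum(c(1, 1), list(), f)[f == 10], 0)
  expect_equal(
    simulatePowerSpectrum(c(0, 2), list(c(10, 0.5, 1)), f)[f == 10], -1.5)
  # a peak evaluated one SD away contributes a * exp(-1/2)
  y <- simulatePowerSpectrum(c(0, 0), list(c(10, 0.8, 2)), f)
  expect_equal(y[f == 12], 0.8 * exp(-0.5))
  # determinism and independence of noise draws
  a <- simulatePowerSpectrum(c(0, 1), list(), f, noiseSD = 0.1, seed = 7)
  expect_identical(a, simulatePowerSpectrum(c(0, 1), list(), f,
                                            noiseSD = 0.1, seed = 7))
  expect_false(identical(a, simulatePowerSpectrum(c(0, 1), list(), f,
                                                  noiseSD = 0.1, seed = 8)))
  expect_error(simulatePowerSpectrum(c(0, 1), list(), c(-1, 2, 3)),
               "positive")
  expect_error(simulatePowerSpectrum(c(NA, 1), list(), f), "finite")
  expect_error(simulatePowerSpectrum(c(0, 1), list(c(10, 1, 0)), f), "width")
})

test_that("time-domain aperiodic signals have the prescribed log-log slope", {
  for (chi in c(0, 2)) {
    x <- simulateAperiodicTimeseries(chi, 0, 500, 60, seed = 42)
    expect_equal(fittedLogLogSlope(x, 500), -chi, tolerance = 0.1,
                 ignore_attr = TRUE)
  }
  expect_identical(simulateAperiodicTimeseries(1, 0, 250, 5, seed = 3),
                   simulateAperiodicTimeseries(1, 0, 250, 5, seed = 3))
  expect_error(simulateAperiodicTimeseries(-0.5, 0, 250, 5), "exponent")
})

test_that("offset raises spectral power tenfold per unit", {
  x0 <- simulateAperiodicTimeseries(1, 0, 500, 40, seed = 11)
  x1 <- simulateAperiodicTimeseries(1, 1, 500, 40, seed = 11)
  p0 <- specsift:::welchPsd(x0, 500)
  p1 <- specsift:::welchPsd(x1, 500)
  sel <- p0$freq >= 2 & p0$freq <= 100
  shift <- mean(log10(p1$psd[sel]) - log10(p0$psd[sel]))
  expect_equal(shift, 1, tolerance = 0.05)
})

test_that("slope recovery is unbiased across exponents", {
  # averaged over seeded realizations per exponent
  for (chi in c(0.5, 1, 1.5, 2)) {
    slopes <- vapply(1:12, function(i) {
      x <- simulateAperiodicTimeseries(chi, 0, 250, 30, seed = 100 + i)
      fittedLogLogSlope(x, 250)
    }, numeric(1))
    expect_lt(abs(mean(slopes) + chi), 0.05)
  }
})

test_that("ex-Gaussian reaction times have the analytic mean and are seeded", {
  rt <- simulateRTs(0.5, 0.05, 0.15, 1e4, seed = 21)
  expect_equal(mean(rt), 0.65, tolerance = 0.011)
  expect_identical(rt, simulateRTs(0.5, 0.05, 0.15, 1e4, seed = 21))
  # near-Gaussian limit has negligible skewness
  rt2 <- simulateRTs(0.5, 0.05, 1e-6, 1e4, seed = 4)
  sk <- mean((rt2 - mean(rt2))^3) / sd(rt2)^3
  expect_lt(abs(sk), 0.2)
  expect_error(simulateRTs(0, 0.05, 0.1, 10), "> 0")
})

test_that("epoch simulation is bit-reproducible and validates its spec", {
  ct <- smallConditionTable()
  spec <- groundTruthSpec(nSubjects = 2, trialsPerCondition = 3,
                          conditionTable = ct, seed = 5)
  e1 <- simulateEpochs(spec)
  e2 <- simulateEpochs(spec)
  expect_identical(e1@samples, e2@samples)
  expect_identical(e1@reactionTimes, e2@reactionTimes)
  expect_true(all(is.finite(e1@samples)))
  expect_error(groundTruthSpec(nSubjects = 2, conditionTable = ct,
                               oscillations = list(list(
                                 freq = 10, amplitude = 1, preLevel = 1,
                                 suppressionOnset = 0.2,
                                 suppressionDuration = 0.5,
                                 suppressionDepth = 1.4, group = "all"))),
               "depth")
  expect_error(groundTruthSpec(nSubjects = 2, conditionTable = ct,
                               erpTemplate = list(amplitude = 1,
                                                  latency = 0.2, width = 0.05,
                                                  group = "nonexistent")),
               "channel group")
})

test_that("suppression depth zero keeps oscillatory power stationary", {
  ct <- smallConditionTable()[1, , drop = FALSE]
  spec <- groundTruthSpec(
    nSubjects = 1, trialsPerCondition = 12, conditionTable = ct,
    oscillations = list(list(freq = 10, amplitude = 3, preLevel = 1,
                             suppressionOnset = 0.2, suppressionDuration = 0.5,
                             suppressionDepth = 0, group = "all")),
    erpTemplate = NULL, exponentEvents = list(), subjectRandomSD = 0,
    sensorNoiseSD = 0.1, seed = 8)
  ep <- simulateEpochs(spec)
  tfr <- tfrEpochs(ep, "morlet", frequencies = c(8, 10, 12))
  interior <- tfr@times > -1 & tfr@times < 2
  p10 <- tfr@power[1, 1, 1, 2, interior]
  expect_lt(sd(p10) / mean(p10), 0.05)
})

test_that("zero-amplitude ERP leaves only averaged-out noise in the ERP", {
  ct <- smallConditionTable()[1, , drop = FALSE]
  spec <- groundTruthSpec(nSubjects = 1, trialsPerCondition = 30,
                          conditionTable = ct, oscillations = list(),
                          erpTemplate = NULL, exponentEvents = list(),
                          aperiodicOffset = -6,  # bury the 1/f track
                          subjectRandomSD = 0, sensorNoiseSD = 0.5, seed = 9)
  ep <- simulateEpochs(spec)
  erp <- computeERP(ep)
  bound <- 3 * 0.5 / sqrt(30)
  vals <- abs(erp@average[1, 1, , ])
  expect_gte(mean(vals <= bound), 0.99)
  expect_lt(max(vals), 1.6 * bound)
})
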