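f350 <- 3:50

test_that("robust aperiodic fit recovers clean spectra and resists peaks", {
  lp <- simulatePowerSpectrum(c(1, 1.5), list(), f350)
  fit <- robustAperiodicFit(f350, lp)
  expect_lt(max(abs(fit - c(1, 1.5))), 1e-6)
  # with a large peak the masked refit beats the naive line fit
  lp2 <- simulatePowerSpectrum(c(0, 1), list(c(10, 1, 1.5)), f350)
  rob <- robustAperiodicFit(f350, lp2)
  naive <- specsift:::simpleAperiodicFit(log10(f350), lp2)
  expect_lt(abs(rob["exponent"] - 1), abs(naive["exponent"] - 1))
  # flat noisy spectra stay near zero exponent (median over seeds)
  errs <- vapply(1:100, function(i) {
    lp3 <- simulatePowerSpectrum(c(0, 0), list(), f350, noiseSD = 0.05,
                                 seed = 1000 + i)
    abs(robustAperiodicFit(f350, lp3)["exponent"])
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  expect_error(robustAperiodicFit(c(1, 2, 3), c(0, 0, 0)), ">= 5")
})

test_that("peak extraction finds interior peaks and applies the edge rule", {
  lp <- simulatePowerSpectrum(c(0, 0), list(c(25, 0.8, 2)), f350)
  pk <- extractPeaks(f350, lp)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk[1, "cf"] - 25), 0.1)
  expect_lt(abs(pk[1, "pw"] - 0.8), 0.05)
  # a peak at the 3 Hz range edge is dropped
  lpe <- simulatePowerSpectrum(c(0, 0), list(c(3, 0.8, 1.5)), f350)
  pke <- extractPeaks(f350, lpe)
  if (nrow(pke)) {
    expect_true(all(pke[, "cf"] >= 3 + pke[, "sd"]))
  } else {
    succeed()
  }
  # all-zero flattened input yields no peaks
  expect_equal(nrow(extractPeaks(f350, rep(0, length(f350)))), 0L)
})

test_that("full spectral fits recover in-model parameters", {
  p <- 10^simulatePowerSpectrum(c(1, 1.5), list(c(10, 0.6, 1.5)), f350)
  m <- fitSpectrum(f350, p)
  expect_lt(abs(m@aperiodic["offset"] - 1), 0.05)
  expect_lt(abs(m@aperiodic["exponent"] - 1.5), 0.05)
  expect_equal(nrow(m@peaks), 1L)
  expect_lt(abs(m@peaks[1, "cf"] - 10), 0.1)
  expect_lt(abs(m@peaks[1, "pw"] - 0.6), 0.05)
  expect_lt(abs(m@peaks[1, "sd"] - 1.5), 0.2)
  # noiseless pure aperiodic is modeled essentially exactly
  m2 <- fitSpectrum(f350, 10^simulatePowerSpectrum(c(1, 1.5), list(), f350))
  expect_gt(m2@rSquared, 0.999)
  expect_lt(m2@mae, 1e-3)
  # two well-separated peaks are both found
  m3 <- fitSpectrum(f350, 10^simulatePowerSpectrum(
    c(0, 1), list(c(10, 0.6, 1.5), c(22, 0.6, 2)), f350))
  expect_equal(nrow(m3@peaks), 2L)
  expect_error(fitSpectrum(f350, c(rep(1, 47), 0)), "positive")
})

test_that("model residual accounting matches the reported error exactly", {
  set.seed(9)
  lp <- simulatePowerSpectrum(c(0.5, 1.2), list(c(11, 0.5, 1.2)), f350,
                              noiseSD = 0.05, seed = 77)
  m <- fitSpectrum(f350, 10^lp)
  model <- m@aperiodic["offset"] - m@aperiodic["exponent"] * log10(f350) +
    reconstructPeriodic(m, f350)
  expect_equal(mean(abs(lp - model)), m@mae, tolerance = 1e-12)
  expect_lte(m@rSquared, 1)
})

test_that("periodic reconstruction is the exact sum of fitted Gaussians", {
  m <- fitSpectrum(f350, 10^simulatePowerSpectrum(c(0, 1), list(), f350))
  expect_equal(reconstructPeriodic(m, f350), rep(0, length(f350)))
  mp <- fitSpectrum(f350,
                    10^simulatePowerSpectrum(c(0, 1), list(c(10, 0.6, 1.5)),
                                             f350))
  cf <- mp@peaks[1, "cf"]; a <- mp@peaks[1, "pw"]; w <- mp@peaks[1, "sd"]
  rec <- reconstructPeriodic(mp, c(cf, cf + w))
  expect_equal(rec[1], a, ignore_attr = TRUE)
  expect_equal(rec[2], a * exp(-0.5), ignore_attr = TRUE)
  expect_true(all(reconstructPeriodic(mp, f350) >= 0))
})

test_that("per-timepoint parameterization recovers planted dynamics", {
  ct <- smallConditionTable()[1, , drop = FALSE]
  # stationary exponent: recovered map is flat in time
  spec <- groundTruthSpec(
    nSubjects = 1, trialsPerCondition = 250, conditionTable = ct,
    aperiodicExponent = 1.2, oscillations = list(), erpTemplate = NULL,
    exponentEvents = list(), subjectRandomSD = 0, sensorNoiseSD = 0.05,
    channelNames = c("Fz", "Pz"), seed = 14)
  tfr <- tfrEpochs(simulateEpochs(spec))
  par <- parameterizeTFR(tfr, timeStride = 5L)
  for (ch in 1:2) {
    expect_lt(sd(par@exponent[1, 1, ch, ]), 0.05)
  }
  # planted exponent bump: channel-average timecourse peaks at its latency
  spec2 <- groundTruthSpec(
    nSubjects = 1, trialsPerCondition = 60, conditionTable = ct,
    oscillations = list(), erpTemplate = NULL,
    exponentEvents = list(list(latency = 0.3, width = 0.15, amplitude = 0.4,
                               group = "all")),
    subjectRandomSD = 0, sensorNoiseSD = 0.05,
    channelNames = c("Fz", "Pz"), seed = 15)
  tfr2 <- tfrEpochs(simulateEpochs(spec2))
  par2 <- parameterizeTFR(tfr2, timeStride = 2L)
  tc <- apply(par2@exponent[1, 1, , ], 2, mean)
  expect_lt(abs(par2@times[which.max(tc)] - 0.3), 0.05)
  # alpha-only input leaves the low-frequency periodic map near zero
  spec3 <- groundTruthSpec(
    nSubjects = 1, trialsPerCondition = 20, conditionTable = ct,
    oscillations = list(list(freq = 10, amplitude = 0.3, preLevel = 1,
                             suppressionOnset = 0.3, suppressionDuration = 0.4,
                             suppressionDepth = 0.4, group = "all")),
    erpTemplate = NULL, exponentEvents = list(), subjectRandomSD = 0,
    sensorNoiseSD = 0.05, channelNames = c("Fz", "Pz"), seed = 16)
  tfr3 <- tfrEpochs(simulateEpochs(spec3))
  par3 <- parameterizeTFR(tfr3, timeStride = 5L)
  low <- par3@frequencies >= 4 & par3@frequencies <= 6
  expect_lt(mean(par3@periodic[1, 1, , low, ], na.rm = TRUE), 0.02)
  # and the alpha peak itself is present pre-suppression
  alpha <- par3@frequencies >= 9 & par3@frequencies <= 11
  preT <- par3@times < 0.2
  expect_gt(mean(par3@periodic[1, 1, , alpha, preT], na.rm = TRUE), 0.1)
})
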