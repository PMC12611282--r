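makeEpochs <- function(samples, fs = 200, times = NULL) {
  d <- dim(samples)
  if (is.null(times)) times <- (seq_len(d[5]) - 1) / fs - 0.5
  new("EpochedData", samples = samples, samplingRate = fs, times = times,
      channelNames = sprintf("ch%d", seq_len(d[4])),
      conditionTable = smallConditionTable()[seq_len(d[2]), , drop = FALSE],
      reactionTimes = array(0.5, dim = d[1:3]),
      accuracy = array(TRUE, dim = d[1:3]),
      subjectIds = sprintf("S%02d", seq_len(d[1])))
}

test_that("ERPs are cell means and subtraction zeroes the trial mean", {
  set.seed(5)
  base <- sin(2 * pi * 5 * seq(0, 1, length.out = 201))
  samples <- array(0, dim = c(1, 1, 6, 2, 201))
  for (r in 1:6) for (ch in 1:2) samples[1, 1, r, ch, ] <- base
  ep <- makeEpochs(samples)
  erp <- computeERP(ep)
  expect_equal(erp@average[1, 1, 1, ], base)
  # subtract and re-average: exactly zero
  sub <- subtractERP(ep, erp)
  erp2 <- computeERP(sub)
  expect_lt(max(abs(erp2@average)), 1e-12)
  # subtracting again changes nothing
  sub2 <- subtractERP(sub, erp2)
  expect_equal(sub2@samples, sub@samples, tolerance = 1e-12)
})

test_that("ERP error shrinks as one over the square root of trial count", {
  set.seed(6)
  sdErr <- function(n) {
    noise <- array(rnorm(n * 100), dim = c(1, 1, n, 1, 100))
    ep <- makeEpochs(noise)
    sd(computeERP(ep)@average)
  }
  e10 <- sdErr(10); e40 <- sdErr(40); e160 <- sdErr(160)
  expect_lt(abs(e10 / e40 - 2) / 2, 0.2)
  expect_lt(abs(e40 / e160 - 2) / 2, 0.2)
})

test_that("random-phase oscillations average out of the ERP", {
  set.seed(7)
  n <- 40; amp <- 2
  t <- seq(0, 1, length.out = 201)
  samples <- array(0, dim = c(1, 1, n, 1, 201))
  for (r in seq_len(n)) {
    samples[1, 1, r, 1, ] <- amp * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  }
  erp <- computeERP(makeEpochs(samples))
  expect_lt(max(abs(erp@average)), 3 * amp / sqrt(n))
})

test_that("subtraction removes evoked power but preserves induced power", {
  set.seed(8)
  fs <- 200
  t <- seq(-0.5, 1.5, by = 1 / fs)
  nT <- length(t); n <- 60
  evoked <- 1.5 * sin(2 * pi * 5 * t) * exp(-(t - 0.3)^2 / (2 * 0.15^2))
  samples <- array(0, dim = c(1, 1, n, 1, nT))
  for (r in seq_len(n)) {
    induced <- sin(2 * pi * 14 * t + runif(1, 0, 2 * pi))
    samples[1, 1, r, 1, ] <- evoked + induced + rnorm(nT, 0, 0.05)
  }
  ep <- makeEpochs(samples, fs = fs, times = t)
  sub <- subtractERP(ep)
  tfr <- tfrEpochs(ep, "morlet", frequencies = c(5, 14), outputRate = 100)
  tfrS <- tfrEpochs(sub, "morlet", frequencies = c(5, 14), outputRate = 100)
  evokedWin <- tfr@times > 0.15 & tfr@times < 0.45
  e0 <- mean(tfr@power[1, 1, 1, 1, evokedWin])
  e1 <- mean(tfrS@power[1, 1, 1, 1, evokedWin])
  expect_lt(e1 / e0, 0.1)  # >= 90% of phase-locked power removed
  mid <- tfr@times > -0.2 & tfr@times < 1.2
  i0 <- mean(tfr@power[1, 1, 1, 2, mid])
  i1 <- mean(tfrS@power[1, 1, 1, 2, mid])
  expect_lt(abs(i1 - i0) / i0, 0.05)  # induced power preserved within 5%
})

test_that("trial-averaged power splits into ERP power plus residual power", {
  set.seed(9)
  fs <- 200
  t <- seq(-0.5, 1.5, by = 1 / fs)
  nT <- length(t); n <- 60
  evoked <- sin(2 * pi * 7 * t) * exp(-(t - 0.3)^2 / (2 * 0.2^2))
  samples <- array(0, dim = c(1, 1, n, 1, nT))
  for (r in seq_len(n)) {
    samples[1, 1, r, 1, ] <- evoked +
      0.8 * sin(2 * pi * 11 * t + runif(1, 0, 2 * pi))
  }
  ep <- makeEpochs(samples, fs = fs, times = t)
  erp <- computeERP(ep)
  res <- subtractERP(ep, erp)
  total <- mean(ep@samples^2)
  parts <- mean(erp@average^2) + mean(res@samples^2)
  expect_lt(abs(total - parts) / total, 0.05)
})

test_that("ERP-exponent coupling maps behave under null and planted links", {
  set.seed(10)
  nS <- 12; nC <- 2; nCh <- 2; nT <- 6
  times <- seq(0, 0.5, length.out = nT)
  erpArr <- array(rnorm(nS * nC * nCh * 11), dim = c(nS, nC, nCh, 11))
  erp <- new("ERPData", average = erpArr,
             times = seq(0, 0.5, length.out = 11),
             nTrials = matrix(10L, nS, nC),
             channelNames = c("a", "b"),
             conditionTable = smallConditionTable(),
             subjectIds = sprintf("S%02d", seq_len(nS)))
  sel <- specsift:::nearestIndex(erp@times, times)
  # null: exponent map independent of the ERP
  expo0 <- array(rnorm(nS * nC * nCh * nT), dim = c(nS, nC, nCh, nT))
  sm0 <- erpAperiodicR2(erp, expo0, times)
  expect_lt(median(abs(sm0@rSquared), na.rm = TRUE), 0.05)
  # planted: exponent = a * ERP + noise, positive R2 throughout
  expo1 <- 0.8 * erpArr[, , , sel] +
    array(rnorm(nS * nC * nCh * nT, 0, 0.1), dim = c(nS, nC, nCh, nT))
  sm1 <- erpAperiodicR2(erp, expo1, times)
  expect_true(all(sm1@rSquared > 0, na.rm = TRUE))
  # zero-variance ERP at a point is flagged missing
  erpz <- erpArr; erpz[, , 1, sel[1]] <- 0
  erp2 <- initialize(erp, average = erpz)
  smz <- erpAperiodicR2(erp2, expo1, times)
  expect_true(is.na(smz@rSquared[1, 1, 1]))
})
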