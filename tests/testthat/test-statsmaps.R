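test_that("BY-FDR matches the brute-force step-up definition", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(3:60, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(byFDR(p, 0.05), bruteForceBY(p, 0.05))
  }
  expect_identical(byFDR(rep(1, 10)), rep(FALSE, 10))
  # a single p exactly at q is rejected (c(1) = 1)
  expect_true(byFDR(0.05, q = 0.05))
  expect_identical(byFDR(c(0.001, 0.01, 0.02, 0.5), 0.05),
                   bruteForceBY(c(0.001, 0.01, 0.02, 0.5), 0.05))
  out <- byFDR(c(0.001, NA, 0.9))
  expect_true(out[1]); expect_true(is.na(out[2])); expect_false(out[3])
})

test_that("cluster filtering keeps runs and simultaneous channels only", {
  m <- matrix(FALSE, 5, 10)
  m[2, 5] <- TRUE  # isolated point
  expect_false(any(clusterFilter(m)))
  m2 <- matrix(FALSE, 5, 10)
  m2[2, 4:6] <- TRUE  # run of exactly three timepoints
  expect_identical(clusterFilter(m2), m2)
  m3 <- matrix(FALSE, 5, 10)
  m3[1:3, 7] <- TRUE  # three channels at one timepoint
  expect_identical(clusterFilter(m3), m3)
  # output never adds points, and matches brute-force enumeration
  set.seed(21)
  for (i in 1:100) {
    mk <- matrix(runif(50) < 0.3, 5, 10)
    got <- clusterFilter(mk)
    expect_identical(got, bruteForceCluster(mk))
    expect_true(all(got <= mk))
  }
  # 3-D masks are filtered within each frequency independently
  arr <- array(FALSE, dim = c(4, 2, 8))
  arr[1, 1, 3:5] <- TRUE
  arr[1, 2, 3] <- TRUE
  got <- clusterFilter(arr)
  expect_true(all(got[1, 1, 3:5]))
  expect_false(any(got[, 2, ]))
})

test_that("ex-Gaussian mu is recovered and filters are applied exactly", {
  errs <- vapply(1:100, function(i) {
    rt <- simulateRTs(0.5, 0.05, 0.15, 1000, seed = 1200 + i)
    abs(exGaussMu(rt)[["mu"]] - 0.5)
  }, numeric(1))
  expect_lt(median(errs), 0.03)
  # anticipations below 200 ms are excluded before fitting
  rt <- simulateRTs(0.5, 0.05, 0.15, 500, seed = 5)
  withAnticipation <- c(rt, 0.1)
  expect_equal(exGaussMu(withAnticipation), exGaussMu(rt), tolerance = 1e-6)
  # a z > 3 outlier is removed within the cell
  withOutlier <- c(rt, mean(rt) + 10 * sd(rt))
  expect_equal(exGaussMu(withOutlier)[["mu"]], exGaussMu(rt)[["mu"]],
               tolerance = 1e-3)
  # near-Gaussian data: mu approaches the sample mean
  rtg <- simulateRTs(0.5, 0.05, 1e-4, 1000, seed = 8)
  expect_lt(abs(exGaussMu(rtg)[["mu"]] - mean(rtg)), 0.02)
  few <- exGaussMu(c(0.4, 0.5, 0.6))
  expect_true(all(is.na(few)))
  expect_identical(attr(few, "flag"), "too_few")
})

test_that("mass-univariate R2 maps separate signal from null", {
  set.seed(61)
  nS <- 15; nC <- 4
  dep <- array(rnorm(nS * nC * 2 * 6), dim = c(nS, nC, 2, 6))
  # planted coupling: predictor = dependent + noise
  prd <- dep + array(rnorm(length(dep), 0, 0.5), dim = dim(dep))
  sm <- massUnivariateR2(dep, prd)
  expect_gt(median(sm@rSquared, na.rm = TRUE), 0.5)
  # independent predictor: negligible shared variance
  prd0 <- array(rnorm(length(dep)), dim = dim(dep))
  sm0 <- massUnivariateR2(dep, prd0)
  expect_lt(median(abs(sm0@rSquared), na.rm = TRUE), 0.05)
  # sign flip under predictor negation, magnitude unchanged
  smn <- massUnivariateR2(dep, -prd)
  expect_equal(smn@rSquared, -sm@rSquared, tolerance = 1e-5)
  # zero-variance predictor points are left missing
  prdz <- prd; prdz[, , 1, 1] <- 1
  smz <- massUnivariateR2(dep, prdz)
  expect_true(is.na(smz@rSquared[1, 1, 1]))
})

test_that("condition comparisons find planted effects where they are", {
  set.seed(71)
  nS <- 20
  labels <- expand.grid(modality = c("vis", "verb"), load = c("l0", "l2"),
                        stimulus = c("nt", "tg"), stringsAsFactors = FALSE)
  nC <- nrow(labels); nCh <- 4
  times <- seq(-0.5, 2, by = 0.1); nT <- length(times)
  arr <- array(rnorm(nS * nC * nCh * nT, 1, 0.1), dim = c(nS, nC, nCh, nT)) +
    array(rnorm(nS, 0, 0.15), dim = c(nS, nC, nCh, nT))
  win <- which(times >= 0.2 & times <= 0.8)
  for (cc in which(labels$stimulus == "tg")) {
    arr[, cc, , win] <- arr[, cc, , win] + 0.2
  }
  rt <- matrix(simulateRTs(0.5, 0.05, 0.15, nS * nC, seed = 3), nS, nC)
  maps <- massUnivariateConditions(arr, labels, rtPerCell = rt, times = times)
  st <- maps[["stimulus1"]]
  expect_gt(sum(st@clusterMask[, , win]), 0)
  expect_equal(sum(st@clusterMask[, , -win]), 0)
  # masks nest: cluster-filtered is a subset of FDR-significant
  for (m in maps) expect_true(all(m@clusterMask <= m@fdrMask))
  # single-level factor is dropped with a notice
  lab1 <- labels; lab1$modality <- "vis"
  expect_message(
    maps1 <- massUnivariateConditions(arr[, , 1, 1, drop = FALSE], lab1,
                                      rtPerCell = rt),
    "single-level")
  expect_false("modality1" %in% names(maps1))
})

test_that("planted reaction-time coupling is recovered by the rt term", {
  set.seed(81)
  nS <- 20
  labels <- expand.grid(modality = c("vis", "verb"), load = c("l0", "l2"),
                        stimulus = c("nt", "tg"), stringsAsFactors = FALSE)
  nC <- nrow(labels); nCh <- 2; nT <- 6
  rt <- matrix(simulateRTs(0.5, 0.08, 0.15, nS * nC, seed = 13), nS, nC)
  rtc <- rt - mean(rt)
  arr <- array(rnorm(nS * nC * nCh * nT, 0, 0.05), dim = c(nS, nC, nCh, nT))
  for (ch in seq_len(nCh)) for (ti in seq_len(nT)) {
    arr[, , ch, ti] <- arr[, , ch, ti] + 0.3 * rtc
  }
  maps <- massUnivariateConditions(arr, labels, rtPerCell = rt)
  expect_lt(abs(median(maps[["rt"]]@coefficient) - 0.3), 0.1)
})
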