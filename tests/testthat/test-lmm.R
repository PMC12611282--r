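test_that("zero between-group variance reproduces ordinary least squares", {
  set.seed(101)
  n <- 240
  subj <- factor(rep(1:30, each = 8))
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, 0, 0.7)
  # force all subject intercepts to be exactly equal
  y <- y - ave(y, subj) + mean(y)
  fit <- fitLMM(y, cbind("(Intercept)" = 1, x = x), list(subject = subj))
  ols <- lm(y ~ x)
  expect_lt(max(abs(fit@beta - coef(ols))), 1e-6)
  st <- satterthwaiteP(fit, "x")
  tt <- summary(ols)$coefficients["x", ]
  expect_lt(abs(st[["p"]] - tt[["Pr(>|t|)"]]), 1e-3)
})

test_that("ML estimates match the mixed-model reference implementation", {
  skip_if_not_installed("lmerTest")
  set.seed(42)
  n <- 240
  subj <- factor(rep(1:30, each = 8))
  x <- rnorm(n)
  y <- 0.5 * x + rep(rnorm(30), each = 8) + rnorm(n, 0, 0.7)
  fit <- fitLMM(y, cbind("(Intercept)" = 1, x = x), list(subject = subj))
  ref <- lmerTest::lmer(y ~ x + (1 | subj), REML = FALSE)
  expect_equal(unname(fit@beta), unname(lme4::fixef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit@varComps),
               as.data.frame(lme4::VarCorr(ref))$vcov, tolerance = 1e-4)
  expect_equal(fit@logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  st <- satterthwaiteP(fit, "x")
  sm <- coef(summary(ref))["x", ]
  expect_equal(st[["se"]], sm[["Std. Error"]], tolerance = 1e-4)
  expect_equal(st[["df"]], sm[["df"]], tolerance = 0.01)
  expect_equal(st[["p"]], sm[["Pr(>|t|)"]], tolerance = 1e-6)
})

test_that("crossed random intercepts match the reference implementation", {
  skip_if_not_installed("lme4")
  set.seed(43)
  d <- expand.grid(s = factor(1:20), c = factor(1:6))
  x <- rnorm(nrow(d))
  y <- 0.4 * x + rnorm(20)[d$s] + 0.5 * rnorm(6)[d$c] +
    rnorm(nrow(d), 0, 0.6)
  fit <- fitLMM(y, cbind("(Intercept)" = 1, x = x),
                list(subject = d$s, condition = d$c))
  ref <- lme4::lmer(y ~ x + (1 | s) + (1 | c),
                    data = cbind(d, x = x, y = y), REML = FALSE)
  expect_equal(unname(fit@beta), unname(lme4::fixef(ref)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(sort(unname(fit@varComps)), sort(vc$vcov), tolerance = 1e-3)
  expect_equal(fit@logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
})

test_that("variance components are recovered in balanced designs", {
  errs <- t(vapply(1:40, function(i) {
    set.seed(500 + i)
    nS <- 200; m <- 10
    subj <- factor(rep(seq_len(nS), each = m))
    y <- rep(rnorm(nS, 0, 1), each = m) + rnorm(nS * m, 0, 1)
    fit <- fitLMM(y, matrix(1, nS * m, 1,
                            dimnames = list(NULL, "(Intercept)")),
                  list(subject = subj))
    abs(fit@varComps - c(1, 1))
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.15)
  expect_lt(median(errs[, 2]), 0.15)
})

test_that("fixed-effect confidence intervals have nominal coverage", {
  hits <- vapply(1:100, function(i) {
    set.seed(700 + i)
    nS <- 40; m <- 4
    subj <- factor(rep(seq_len(nS), each = m))
    g <- rep(rep(c(-0.5, 0.5), each = m / 2), nS)
    y <- 0.5 * g + rep(rnorm(nS, 0, 0.6), each = m) + rnorm(nS * m, 0, 0.8)
    fit <- fitLMM(y, cbind("(Intercept)" = 1, g = g), list(subject = subj))
    st <- satterthwaiteP(fit, "g")
    half <- qt(0.975, st[["df"]]) * st[["se"]]
    abs(st[["estimate"]] - 0.5) <= half
  }, logical(1))
  expect_gte(sum(hits), 93)
})

test_that("Satterthwaite df approaches the classical between-subject df", {
  set.seed(31)
  nS <- 200; m <- 5
  subj <- factor(rep(seq_len(nS), each = m))
  xs <- rep(rnorm(nS), each = m)  # between-subject predictor
  y <- 0.3 * xs + rep(rnorm(nS), each = m) + rnorm(nS * m, 0, 0.5)
  fit <- fitLMM(y, cbind("(Intercept)" = 1, x = xs), list(subject = subj))
  st <- satterthwaiteP(fit, "x")
  expect_lt(abs(st[["df"]] - (nS - 2)) / (nS - 2), 0.05)
  # p decreases as |t| grows at fixed df
  ps <- 2 * pt(-abs(c(1, 2, 3)), df = st[["df"]])
  expect_true(all(diff(ps) < 0))
})

test_that("signed marginal R-squared follows its definition", {
  set.seed(55)
  n <- 160
  subj <- factor(rep(1:20, each = 8))
  x <- rnorm(n)
  # a predictor orthogonalized within every subject block gives beta = 0
  y0 <- rnorm(n)
  for (s in levels(subj)) {
    i <- subj == s
    y0[i] <- residuals(lm(y0[i] ~ x[i]))
  }
  fit0 <- fitLMM(y0, cbind("(Intercept)" = 1, x = x), list(subject = subj))
  expect_equal(marginalR2(fit0, "x"), 0, tolerance = 1e-8)
  # y identical to the predictor saturates at 1
  fit1 <- fitLMM(x, cbind("(Intercept)" = 1, x = x), list(subject = subj))
  expect_gte(marginalR2(fit1, "x"), 0.999)
  # negating the predictor flips only the sign
  fitp <- fitLMM(0.8 * x + rnorm(n, 0, 0.5),
                 cbind("(Intercept)" = 1, x = x), list(subject = subj))
  y2 <- fitp@model$y
  fitn <- fitLMM(y2, cbind("(Intercept)" = 1, x = -x), list(subject = subj))
  expect_equal(marginalR2(fitn, "x"), -marginalR2(fitp, "x"),
               tolerance = 1e-6)
  # affine rescaling of y leaves the magnitude unchanged
  fitS <- fitLMM(3 * y2 + 10, cbind("(Intercept)" = 1, x = x),
                 list(subject = subj))
  expect_equal(abs(marginalR2(fitS, "x")), abs(marginalR2(fitp, "x")),
               tolerance = 1e-6)
})

test_that("marginal R-squared magnitude tracks the plug-in truth", {
  # sigma_f^2 = 1, sigma_gamma^2 = 1, sigma_e^2 = 2 -> R2 = 0.25
  r2s <- vapply(1:60, function(i) {
    set.seed(900 + i)
    nS <- 50; m <- 8
    subj <- factor(rep(seq_len(nS), each = m))
    x <- rnorm(nS * m)
    y <- x + rep(rnorm(nS, 0, 1), each = m) + rnorm(nS * m, 0, sqrt(2))
    fit <- fitLMM(y, cbind("(Intercept)" = 1, x = x), list(subject = subj))
    abs(marginalR2(fit, "x"))
  }, numeric(1))
  expect_lt(abs(median(r2s) - 0.25), 0.05)
})

test_that("degenerate designs raise informative errors", {
  y <- rnorm(20)
  subj <- factor(rep(1:5, each = 4))
  X <- cbind("(Intercept)" = 1, a = rep(1, 20))
  expect_error(fitLMM(y, X, list(subject = subj)), "aliased")
  expect_error(fitLMM(y, cbind(1), list(g = factor(rep(1, 20)))),
               ">= 2 groups")
})
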