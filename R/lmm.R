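# ---- profiled maximum-likelihood machinery -------------------------------

# Single random intercept: closed-form profile of beta and sigma_e^2 given
# the variance ratio lambda = sigma_g^2 / sigma_e^2, using group sums only.
profileSingle <- function(lambda, pre) {
  cg <- lambda / (1 + lambda * pre$ng)
  A <- pre$XtX - crossprod(pre$Sx * sqrt(cg))
  b <- pre$Xty - colSums(pre$Sx * (cg * pre$Sy))
  yy <- pre$yty - sum(cg * pre$Sy^2)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- max(yy - 2 * sum(beta * b) + drop(crossprod(beta, A %*% beta)),
             1e-300)
  n <- pre$n
  s2 <- rss / n
  nll <- 0.5 * (n * log(2 * pi * s2) + sum(log1p(lambda * pre$ng)) + n)
  list(nll = nll, beta = beta, s2 = s2, A = A)
}

# General path: V0 = I + sum_k lambda_k Zk Zk' via dense Cholesky.
profileGeneral <- function(lambda, y, X, ZZt) {
  n <- length(y)
  V0 <- diag(n)
  for (k in seq_along(ZZt)) V0 <- V0 + lambda[k] * ZZt[[k]]
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdet <- 2 * sum(log(diag(R)))
  # whiten once: Xi = R^-T X so that crossprod(Xi) = X' V0^-1 X
  Xi <- forwardsolve(t(R), X)
  yi <- forwardsolve(t(R), y)
  A <- crossprod(Xi)
  b <- crossprod(Xi, yi)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  r <- yi - Xi %*% beta
  s2 <- max(sum(r^2) / n, 1e-300)
  nll <- 0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(nll = nll, beta = drop(beta), s2 = s2, A = A)
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + sum_k Z_k u_k + e` with independent random
#' intercepts for one or two (crossed) grouping factors, by maximum
#' likelihood: the variance ratios `lambda_k = sigma_k^2 / sigma_e^2` are
#' profiled (closed-form group-sum path for a single factor, Cholesky of
#' the marginal covariance for crossed factors) and `beta`, `sigma_e^2`
#' follow in closed form. Missing cells are handled by simply using the
#' available rows.
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix (including the intercept column).
#' @param groups list of one or two factors (each `length(y)`), the random
#'   intercept groupings; each must have >= 2 levels present.
#' @return an [LMMFit-class].
#' @export
fitLMM <- function(y, X, groups) {
  X <- as.matrix(X)
  if (is.factor(groups) || is.character(groups)) groups <- list(groups)
  groups <- lapply(groups, function(g) droplevels(factor(g)))
  keep <- is.finite(y) & apply(is.finite(X), 1, all)
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    groups <- lapply(groups, function(g) droplevels(g[keep]))
  }
  n <- length(y)
  for (g in groups) {
    if (nlevels(g) < 2L) stop("each random factor needs >= 2 groups",
                              call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    aliased <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("singular fixed-effects design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  nG <- length(groups)
  if (nG == 1L) {
    g <- groups[[1]]
    idx <- split(seq_len(n), g)
    Sx <- do.call(rbind, lapply(idx, function(i) colSums(X[i, , drop = FALSE])))
    pre <- list(n = n, ng = lengths(idx), XtX = crossprod(X),
                Xty = drop(crossprod(X, y)), yty = sum(y^2),
                Sx = Sx, Sy = vapply(idx, function(i) sum(y[i]), numeric(1)))
    obj <- function(th) {
      p <- profileSingle(exp(th), pre)
      if (is.null(p)) 1e10 else p$nll
    }
    opt <- optimize(obj, c(-16, 12), tol = 1e-8)
    lam <- exp(opt$minimum)
    prof <- profileSingle(lam, pre)
    lambdas <- lam
  } else {
    ZZt <- lapply(groups, function(g) tcrossprod(model.matrix(~ g - 1)))
    obj <- function(th) {
      p <- profileGeneral(exp(th), y, X, ZZt)
      if (is.null(p)) 1e10 else p$nll
    }
    opt <- optim(rep(log(0.5), nG), obj, method = "L-BFGS-B",
                 lower = rep(-16, nG), upper = rep(12, nG),
                 control = list(maxit = 200))
    lambdas <- exp(opt$par)
    prof <- profileGeneral(lambdas, y, X, ZZt)
  }
  if (is.null(prof)) {
    return(new("LMMFit", beta = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               vcovBeta = matrix(NA_real_, ncol(X), ncol(X)),
               varComps = numeric(0), sigmaF2 = NA_real_, logLik = NA_real_,
               nobs = n, model = list(), converged = FALSE))
  }
  s2 <- prof$s2
  vc <- c(lambdas * s2, s2)
  names(vc) <- c(paste0("group", seq_len(nG)), "residual")
  gn <- names(groups)
  if (!is.null(gn) && all(nzchar(gn))) names(vc)[seq_len(nG)] <- gn
  beta <- setNames(drop(prof$beta), colnames(X))
  fittedFix <- drop(X %*% beta)
  new("LMMFit",
      beta = beta,
      vcovBeta = s2 * solve(prof$A),
      varComps = pmax(vc, 0),
      sigmaF2 = var(fittedFix) * (n - 1) / n,
      logLik = -prof$nll,
      nobs = as.integer(n),
      model = list(y = y, X = X, groups = groups),
      converged = TRUE)
}

#' Signed marginal R-squared of a mixed-model fit
#'
#' The proportion of total variance explained by the fixed effects,
#' `sigma_f^2 / (sigma_f^2 + sum_k sigma_k^2 + sigma_e^2)`, where
#' `sigma_f^2` is the variance of the fixed-effect predictions, signed by
#' the focal fixed-effect coefficient (the single predictor in
#' correlation-style models). Defined as 0 when all variances vanish.
#'
#' @param fit an [LMMFit-class].
#' @param focal name or index of the focal coefficient supplying the sign
#'   (default: the first non-intercept coefficient).
#' @return signed value in `[-1, 1]`.
#' @export
marginalR2 <- function(fit, focal = NULL) {
  if (!fit@converged) return(NA_real_)
  tot <- fit@sigmaF2 + sum(fit@varComps)
  if (tot <= 0) return(0)
  mag <- fit@sigmaF2 / tot
  if (is.null(focal)) {
    nonint <- which(names(fit@beta) != "(Intercept)")
    focal <- if (length(nonint)) nonint[1] else 1L
  }
  sgn <- sign(fit@beta[[focal]])
  if (sgn == 0) sgn <- 1
  unname(mag * sgn)
}

# Finite-difference gradient and Hessian (central differences).
fdGrad <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

fdHess <- function(f, x, h) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1L):p) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# Negative log-likelihood and coefficient variances as functions of the
# variance components (beta profiled), for Satterthwaite inference.
lmmThetaFunctions <- function(fit) {
  y <- fit@model$y; X <- fit@model$X; groups <- fit@model$groups
  n <- length(y)
  ZZt <- lapply(groups, function(g) tcrossprod(model.matrix(~ g - 1)))
  buildV <- function(theta) {
    V <- diag(theta[length(theta)], n)
    for (k in seq_along(ZZt)) V <- V + theta[k] * ZZt[[k]]
    V
  }
  list(
    negLL = function(theta) {
      R <- tryCatch(chol(buildV(theta)), error = function(e) NULL)
      if (is.null(R)) return(1e10)
      Xi <- forwardsolve(t(R), X)
      yi <- forwardsolve(t(R), y)
      A <- crossprod(Xi)
      beta <- solve(A, crossprod(Xi, yi))
      r <- yi - Xi %*% beta
      0.5 * (2 * sum(log(diag(R))) + n * log(2 * pi) + sum(r^2))
    },
    varAll = function(theta) {
      R <- tryCatch(chol(buildV(theta)), error = function(e) NULL)
      if (is.null(R)) return(rep(NA_real_, ncol(X)))
      Xi <- forwardsolve(t(R), X)
      diag(solve(crossprod(Xi)))
    }
  )
}

#' Satterthwaite tests for every fixed effect of a fit
#'
#' Same approximation as [satterthwaiteP()], computed for all coefficients
#' at once: the Hessian of the ML negative log-likelihood and the
#' coefficient-variance gradients are shared across coefficients, which is
#' what makes mass-univariate maps affordable.
#'
#' @param fit an [LMMFit-class].
#' @return matrix with one row per coefficient and columns `estimate`,
#'   `se`, `t`, `df`, `p`.
#' @export
satterthwaiteTable <- function(fit) {
  p <- length(fit@beta)
  out <- matrix(NA_real_, p, 5,
                dimnames = list(names(fit@beta),
                                c("estimate", "se", "t", "df", "p")))
  out[, "estimate"] <- fit@beta
  if (!fit@converged) return(out)
  theta <- fit@varComps
  fns <- lmmThetaFunctions(fit)
  scale <- max(theta["residual"], 1e-12)
  free <- which(theta > 1e-6 * scale)
  if (!length(free)) free <- length(theta)
  h <- pmax(1e-4 * abs(theta[free]), 1e-10)
  f0 <- fns$varAll(theta)
  # gradient of every coefficient variance wrt each free component
  G <- matrix(NA_real_, length(free), p)
  for (i in seq_along(free)) {
    tp <- theta; tp[free[i]] <- theta[free[i]] + h[i]
    tm <- theta; tm[free[i]] <- max(theta[free[i]] - h[i], 1e-12)
    G[i, ] <- (fns$varAll(tp) - fns$varAll(tm)) / (tp[free[i]] - tm[free[i]])
  }
  nllFree <- function(tf) {
    th <- theta; th[free] <- pmax(tf, 1e-12)
    fns$negLL(th)
  }
  H <- fdHess(nllFree, theta[free], h)
  Ainv <- tryCatch(solve(H), error = function(e) NULL)
  for (j in seq_len(p)) {
    if (!is.finite(f0[j]) || f0[j] <= 0) next
    denom <- if (is.null(Ainv)) NA_real_ else drop(t(G[, j]) %*% Ainv %*% G[, j])
    df <- if (is.finite(denom) && denom > 0) 2 * f0[j]^2 / denom else Inf
    if (!is.finite(df) || df <= 0) df <- Inf
    se <- sqrt(f0[j])
    tv <- fit@beta[[j]] / se
    out[j, c("se", "t", "df", "p")] <- c(se, tv, df, 2 * pt(-abs(tv), df))
  }
  out
}

#' Satterthwaite-approximated test of a fixed effect
#'
#' Computes the t statistic of one coefficient of an ML mixed-model fit
#' together with Satterthwaite-approximated denominator degrees of
#' freedom: `df = 2 f(theta)^2 / (g' A g)` where `f` is the coefficient's
#' sampling variance as a function of the variance components, `g` its
#' gradient at the estimates, and `A` the asymptotic covariance of the
#' variance-component estimates (inverse Hessian of the ML negative
#' log-likelihood). Variance components estimated at the zero boundary are
#' held fixed in the approximation.
#'
#' @param fit an [LMMFit-class].
#' @param coefficient name or index of the fixed effect to test.
#' @return named numeric `c(estimate, se, t, df, p)` (two-sided p).
#' @export
satterthwaiteP <- function(fit, coefficient) {
  if (!fit@converged) {
    return(c(estimate = NA, se = NA, t = NA, df = NA, p = NA))
  }
  j <- if (is.character(coefficient)) match(coefficient, names(fit@beta))
       else as.integer(coefficient)
  if (is.na(j)) stop("unknown coefficient", call. = FALSE)
  tab <- satterthwaiteTable(fit)
  setNames(tab[j, ], colnames(tab))
}
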