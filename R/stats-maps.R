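#' Benjamini-Yekutieli FDR significance mask
#'
#' Step-up procedure with the harmonic correction `c(m) = sum_{i=1}^m 1/i`
#' valid under arbitrary dependence: reject the ordered p-values
#' `p_(1) <= ... <= p_(k)` for the largest k with
#' `p_(k) <= k q / (m c(m))`. Missing p-values are excluded from m and
#' returned as NA.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param q FDR level.
#' @return logical vector of rejections (NA where p was NA).
#' @export
byFDR <- function(p, q = 0.05) {
  out <- rep(NA, length(p))
  ok <- which(is.finite(p))
  if (!length(ok)) return(out)
  out[ok] <- p.adjust(p[ok], method = "BY") <= q
  out
}

# Runs of >= k consecutive TRUEs in a logical vector.
runMask <- function(x, k) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  r$values <- r$values & r$lengths >= k
  inverse.rle(r)
}

#' Cluster-extent filter for significance masks
#'
#' Retains a significant channel x timepoint only if it belongs to a run
#' of at least `minTime` consecutive significant timepoints at its channel,
#' or at least `minChannels` channels are simultaneously significant at
#' its timepoint (both evaluated within the same frequency). Channels are
#' counted without a spatial-adjacency requirement. Never adds points.
#'
#' @param mask logical array `[channel, time]` or `[channel, freq, time]`.
#' @param minTime,minChannels minimum cluster extents (default 3).
#' @return logical array of the same shape.
#' @export
clusterFilter <- function(mask, minTime = 3L, minChannels = 3L) {
  d <- dim(mask)
  if (is.null(d) || length(d) == 2L) {
    m <- if (is.null(d)) matrix(mask, nrow = 1L) else mask
    m[is.na(m)] <- FALSE
    timeRuns <- t(apply(m, 1, runMask, k = minTime))
    if (ncol(m) == 1L) timeRuns <- matrix(timeRuns, ncol = 1L)
    simult <- matrix(rep(colSums(m) >= minChannels, each = nrow(m)),
                     nrow = nrow(m))
    out <- m & (timeRuns | simult)
    if (is.null(d)) out <- as.vector(out)
    return(out)
  }
  if (length(d) == 3L) {
    out <- mask
    for (f in seq_len(d[2])) {
      m2 <- array(mask[, f, ], dim = d[c(1, 3)])
      out[, f, ] <- clusterFilter(m2, minTime, minChannels)
    }
    return(out)
  }
  stop("mask must be [channel, time] or [channel, freq, time]", call. = FALSE)
}

# ex-Gaussian density (Normal(mu, sigma) + Exp(mean tau)), log scale.
dexgaussLog <- function(x, mu, sigma, tau) {
  z <- (x - mu) / sigma
  -log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    pnorm(z - sigma / tau, log.p = TRUE)
}

#' Ex-Gaussian reaction-time summary
#'
#' Filters reaction times (removes within-cell |z| > 3 outliers and
#' anticipations below 0.2 s), then fits the ex-Gaussian distribution by
#' maximum likelihood with moment-based starting values. `mu`, which
#' approximates the distribution mode, is the designated cell summary.
#'
#' @param rts reaction times in seconds.
#' @param minN minimum number of reaction times required after filtering.
#' @return named numeric `c(mu, sigma, tau)`, all NA (with attribute
#'   `flag = "too_few"`) when fewer than `minN` values survive filtering.
#' @export
exGaussMu <- function(rts, minN = 10L) {
  rts <- rts[is.finite(rts)]
  if (length(rts) > 1L && sd(rts) > 0) {
    z <- (rts - mean(rts)) / sd(rts)
    rts <- rts[z <= 3]
  }
  rts <- rts[rts >= 0.2]
  if (length(rts) < minN) {
    out <- c(mu = NA_real_, sigma = NA_real_, tau = NA_real_)
    attr(out, "flag") <- "too_few"
    return(out)
  }
  m <- mean(rts); s <- sd(rts)
  sk <- mean((rts - m)^3) / s^3
  tau0 <- max(s * (max(sk, 0.01) / 2)^(1 / 3), 1e-3)
  start <- c(m - tau0, max(sqrt(max(s^2 - tau0^2, 1e-6)), 1e-3), tau0)
  nll <- function(p) -sum(dexgaussLog(rts, p[1], p[2], p[3]))
  opt <- optim(start, nll, method = "L-BFGS-B",
               lower = c(-Inf, 1e-4, 1e-4),
               control = list(maxit = 500))
  c(mu = opt$par[1], sigma = opt$par[2], tau = opt$par[3])
}

# Sum-to-zero-coded design for modality*load*stimulus + centered rt.
conditionDesign <- function(df, withRT = TRUE) {
  fac <- c("modality", "load", "stimulus")
  keepFac <- fac[vapply(fac, function(f) length(unique(df[[f]])) > 1L,
                        logical(1))]
  dropped <- setdiff(fac, keepFac)
  if (length(dropped)) {
    message("dropping single-level factor(s): ",
            paste(dropped, collapse = ", "))
  }
  for (f in keepFac) df[[f]] <- factor(df[[f]])
  rhs <- if (length(keepFac)) paste(keepFac, collapse = " * ") else "1"
  if (withRT && "rt" %in% names(df) && any(is.finite(df$rt))) {
    df$rt <- df$rt - mean(df$rt, na.rm = TRUE)
    rhs <- paste(rhs, "+ rt")
  }
  ctr <- lapply(setNames(keepFac, keepFac), function(f) "contr.sum")
  X <- model.matrix(as.formula(paste("~", rhs)), df,
                    contrasts.arg = if (length(keepFac)) ctr else NULL)
  X
}

newStatMap <- function(term, shape, channelNames, frequencies, times) {
  a <- array(NA_real_, dim = shape)
  m <- array(FALSE, dim = shape)
  new("StatMap", term = term, coefficient = a, rSquared = a, p = a,
      fdrMask = m, clusterMask = m, channelNames = channelNames,
      frequencies = frequencies, times = times)
}

# Coerce a [subject, condition, channel(, freq), time] map to 5-D with an
# explicit singleton frequency axis when absent.
as5d <- function(map) {
  d <- dim(map)
  if (length(d) == 4L) {
    map <- array(map, dim = c(d[1:3], 1L, d[4]))
  } else if (length(d) != 5L) {
    stop("map must be [subject, condition, channel(, freq), time]",
         call. = FALSE)
  }
  map
}

#' Mass-univariate signed marginal R-squared map
#'
#' At every channel(-frequency)-timepoint, fits the mixed model
#' `dependent ~ predictor + (1 | subject) + (1 | condition)` across the
#' subject x condition observations and stores the signed marginal
#' R-squared (sign from the predictor coefficient). Points whose fit fails
#' or whose predictor has zero variance are left NA.
#'
#' @param dependent,predictor arrays
#'   `[subject, condition, channel(, freq), time]` with matching shape.
#' @param channelNames,frequencies,times axis metadata (optional).
#' @return a [StatMap-class] with the `rSquared` and `coefficient` maps
#'   filled.
#' @export
massUnivariateR2 <- function(dependent, predictor, channelNames = NULL,
                             frequencies = NULL, times = NULL) {
  dep <- as5d(dependent); pred <- as5d(predictor)
  if (!all(dim(dep) == dim(pred))) stop("map shapes differ", call. = FALSE)
  d <- dim(dep)
  nS <- d[1]; nC <- d[2]
  subj <- factor(rep(seq_len(nS), times = nC))
  cond <- factor(rep(seq_len(nC), each = nS))
  shape <- d[3:5]
  sm <- newStatMap("predictor", shape,
                   channelNames %||% sprintf("ch%02d", seq_len(d[3])),
                   frequencies %||% seq_len(d[4]),
                   times %||% seq_len(d[5]))
  for (ch in seq_len(d[3])) for (fi in seq_len(d[4])) for (ti in seq_len(d[5])) {
    y <- as.vector(dep[, , ch, fi, ti])
    x <- as.vector(pred[, , ch, fi, ti])
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 4L || sd(x[ok]) == 0) next
    X <- cbind("(Intercept)" = 1, predictor = x)
    fit <- tryCatch(
      fitLMM(y[ok], X[ok, , drop = FALSE],
             list(subject = subj[ok], condition = cond[ok])),
      error = function(e) NULL)
    if (is.null(fit) || !fit@converged) next
    sm@rSquared[ch, fi, ti] <- marginalR2(fit, "predictor")
    sm@coefficient[ch, fi, ti] <- fit@beta[["predictor"]]
  }
  sm
}

#' Mass-univariate condition comparison
#'
#' At every channel(-frequency)-timepoint, fits
#' `y ~ 1 + modality * load * stimulus + rt + (1 | subject)` by maximum
#' likelihood across the subject x condition observations (with
#' sum-to-zero factor coding and the cell-level ex-Gaussian mu reaction
#' time, mean-centered), computes Satterthwaite p-values per fixed-effect
#' term, applies Benjamini-Yekutieli FDR at level `q` across the map of
#' each term, and then the cluster-extent filter. Single-level factors are
#' dropped with a notice.
#'
#' @param map dependent array `[subject, condition, channel(, freq), time]`
#'   (e.g. an exponent map or band periodic power).
#' @param labels condition data.frame with columns `modality`, `load`,
#'   `stimulus` (one row per condition).
#' @param rtPerCell matrix `[subject, condition]` of ex-Gaussian mu values
#'   (NULL to omit the rt covariate).
#' @param q FDR level.
#' @param minTime,minChannels cluster-filter extents.
#' @param channelNames,frequencies,times axis metadata (optional).
#' @return named list of [StatMap-class], one per fixed-effect term
#'   (intercept excluded).
#' @export
massUnivariateConditions <- function(map, labels, rtPerCell = NULL, q = 0.05,
                                     minTime = 3L, minChannels = 3L,
                                     channelNames = NULL, frequencies = NULL,
                                     times = NULL) {
  dep <- as5d(map)
  d <- dim(dep)
  nS <- d[1]; nC <- d[2]
  if (nrow(labels) != nC) stop("labels must match the condition axis",
                               call. = FALSE)
  base <- data.frame(
    subject = factor(rep(seq_len(nS), times = nC)),
    modality = rep(labels$modality, each = nS),
    load = rep(labels$load, each = nS),
    stimulus = rep(labels$stimulus, each = nS),
    stringsAsFactors = FALSE
  )
  base$rt <- if (is.null(rtPerCell)) NA_real_ else as.vector(rtPerCell)
  X <- conditionDesign(base, withRT = !is.null(rtPerCell))
  terms <- setdiff(colnames(X), "(Intercept)")
  shape <- d[3:5]
  maps <- lapply(terms, newStatMap, shape = shape,
                 channelNames = channelNames %||% sprintf("ch%02d", seq_len(d[3])),
                 frequencies = frequencies %||% seq_len(d[4]),
                 times = times %||% seq_len(d[5]))
  names(maps) <- terms
  for (ch in seq_len(d[3])) for (fi in seq_len(d[4])) for (ti in seq_len(d[5])) {
    y <- as.vector(dep[, , ch, fi, ti])
    ok <- is.finite(y) & apply(is.finite(X), 1, all)
    if (sum(ok) < ncol(X) + 2L) next
    fit <- tryCatch(fitLMM(y[ok], X[ok, , drop = FALSE],
                           list(subject = base$subject[ok])),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@converged) next
    tab <- satterthwaiteTable(fit)
    for (tm in terms) {
      maps[[tm]]@coefficient[ch, fi, ti] <- tab[tm, "estimate"]
      maps[[tm]]@p[ch, fi, ti] <- tab[tm, "p"]
    }
  }
  for (tm in terms) {
    pv <- maps[[tm]]@p
    mask <- array(byFDR(as.vector(pv), q), dim = dim(pv))
    mask[is.na(mask)] <- FALSE
    maps[[tm]]@fdrMask <- mask
    maps[[tm]]@clusterMask <- clusterFilter(mask, minTime, minChannels)
  }
  maps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
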