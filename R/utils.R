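#' @importFrom stats approx as.formula coef cor median model.matrix optim
#'   optimize p.adjust pnorm pt quantile rexp rnorm runif sd setNames var
#'   fft mvfft nextn
#' @importFrom utils modifyList head tail str capture.output packageVersion
NULL

# Derive a reproducible 32-bit substream seed from a master seed.
# Streams indexed by one or more small integers; collisions are avoided by
# mixing with distinct large primes and reducing modulo 2^31 - 1.
deriveSeed <- function(master, ...) {
  idx <- c(...)
  if (length(idx) == 0L) idx <- 0L
  s <- as.double(master) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopIfNotFinite <- function(x, label) {
  if (!all(is.finite(x))) {
    stop("non-finite values in ", label, call. = FALSE)
  }
  invisible(TRUE)
}

# Nearest index of `value` on an increasing grid.
nearestIndex <- function(grid, value) {
  vapply(value, function(v) which.min(abs(grid - v)), integer(1))
}

# Uniformity check for a time axis (relative tolerance on the step).
isUniformAxis <- function(x, tol = 1e-6) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  max(abs(d - d[1])) <= tol * abs(d[1])
}

# Centered moving average via cumulative sums (window of w samples).
movingAverage <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Welch power spectral density by averaged modified periodograms
# (Hann window, 50% overlap). Returns data.frame(freq, psd).
welchPsd <- function(x, fs, segLength = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(segLength)) segLength <- min(n, round(4 * fs))
  segLength <- min(segLength, n)
  hop <- max(1L, floor(segLength * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, segLength - 1) / segLength)
  starts <- seq(1L, n - segLength + 1L, by = hop)
  u <- sum(w^2)
  acc <- numeric(floor(segLength / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)] * w
    p <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_along(acc)]
  }
  psd <- acc / length(starts)
  freq <- (seq_along(psd) - 1L) * fs / segLength
  data.frame(freq = freq, psd = psd)
}
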