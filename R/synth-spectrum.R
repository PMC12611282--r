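#' Simulate a power spectrum from the spectral model
#'
#' Evaluates the semi-log spectral model directly: a linear aperiodic
#' component in log10-frequency, `b - chi * log10(f)`, plus a sum of
#' Gaussian peaks `a * exp(-(f - c)^2 / (2 w^2))`, with optional
#' independent Gaussian noise per frequency. This is the exact generative
#' model the spectral parameterization inverts, so noiseless output is
#' recovered to machine precision by construction.
#'
#' @param aperiodic numeric length-2 `c(offset, exponent)`.
#' @param peaks list of numeric length-3 `c(cf, pw, sd)` vectors (or an
#'   n x 3 matrix); may be empty.
#' @param freqs strictly increasing positive frequency grid (Hz).
#' @param noiseSD SD of additive Gaussian noise, log10-power units.
#' @param seed integer seed (only used when `noiseSD > 0`).
#' @return numeric vector of log10-power per frequency.
#' @examples
#' f <- 3:50
#' simulatePowerSpectrum(c(1, 1), list(), f)[f == 10]  # 1 - log10(10) = 0
#' @export
simulatePowerSpectrum <- function(aperiodic, peaks = list(), freqs,
                                  noiseSD = 0, seed = 1L) {
  if (any(freqs <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (is.matrix(peaks)) peaks <- split(peaks, row(peaks))
  pars <- c(aperiodic, unlist(peaks), noiseSD)
  if (!all(is.finite(pars))) stop("non-finite parameter", call. = FALSE)
  if (noiseSD < 0) stop("noiseSD must be >= 0", call. = FALSE)
  y <- aperiodic[1] - aperiodic[2] * log10(freqs)
  for (pk in peaks) {
    if (pk[3] <= 0) stop("peak width must be > 0", call. = FALSE)
    y <- y + pk[2] * exp(-(freqs - pk[1])^2 / (2 * pk[3]^2))
  }
  if (noiseSD > 0) {
    y <- y + withSeed(seed, rnorm(length(freqs), 0, noiseSD))
  }
  unname(y)
}

#' Simulate a time-domain signal with a prescribed 1/f spectrum
#'
#' Synthesizes a real-valued signal whose short-time spectrum follows the
#' aperiodic model `10^(b - chi * log10 f)` with possibly time-varying
#' exponent and offset. Synthesis is short-time inverse-FFT: overlapping
#' windows (default 1 s, 50% overlap) are filled with the target amplitude
#' spectrum and uniform-random phases, weighted with a square-root-Hann
#' window (so window powers overlap-add to a constant) and summed. The
#' exponent/offset for each window are taken at its center time.
#'
#' @param exponent scalar or vector chi(t) sampled at `samplingRate`
#'   (recycled/interpolated to the signal length); must be >= 0.
#' @param offset scalar or vector b(t), log10-power units.
#' @param samplingRate Hz.
#' @param duration seconds (> 0). Signal length is
#'   `round(duration * samplingRate)` samples.
#' @param seed integer seed; output is deterministic given the seed.
#' @param windowSec synthesis window length in seconds.
#' @return numeric signal vector.
#' @export
simulateAperiodicTimeseries <- function(exponent, offset = 0, samplingRate,
                                        duration, seed = 1L, windowSec = 1) {
  if (any(exponent < 0)) stop("exponent must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  n <- round(duration * samplingRate)
  chiT <- if (length(exponent) == 1L) rep(exponent, n) else
    approx(seq_along(exponent), exponent, n = n)$y
  bT <- if (length(offset) == 1L) rep(offset, n) else
    approx(seq_along(offset), offset, n = n)$y
  withSeed(seed, {
    L <- max(8L, 2L * floor(windowSec * samplingRate / 2))
    hop <- L %/% 2L
    # sqrt-Hann: squared windows overlap-add to 1 at 50% overlap, keeping
    # the synthesized power stationary across window seams
    w <- sqrt(0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L))
    nyq <- L %/% 2L
    fpos <- (1:(nyq - 1L)) * samplingRate / L
    # pad one window on each side so edges get full overlap coverage; the
    # grid origin is jittered per realization so window-seam structure is
    # not locked to fixed epoch positions across trials
    jit <- sample.int(hop, 1L) - 1L
    starts <- seq(-hop + 1L - jit, n, by = hop)
    out <- numeric(n + 2L * L)
    off0 <- L  # offset of sample 1 in `out`
    for (s in starts) {
      ctr <- min(max(s + hop, 1L), n)
      amp <- 10^((bT[ctr] - chiT[ctr] * log10(fpos)) / 2)
      ph <- runif(nyq - 1L, 0, 2 * pi)
      spec <- complex(length.out = L)
      spec[2:nyq] <- amp * exp(1i * ph)
      spec[(nyq + 2L):L] <- Conj(spec[nyq:2])
      seg <- Re(fft(spec, inverse = TRUE)) / sqrt(L)
      out[(off0 + s):(off0 + s + L - 1L)] <- out[(off0 + s):(off0 + s + L - 1L)] + seg * w
    }
    out[(off0 + 1L):(off0 + n)]
  })
}
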