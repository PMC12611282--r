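# Complex Morlet wavelet, unit energy, truncated at +/- 3.5 temporal SDs.
# Returns list(w = complex taps, half = half-length in samples).
morletWavelet <- function(freq, nCycles, fs) {
  sdT <- nCycles / (2 * pi * freq)
  half <- max(1L, ceiling(3.5 * sdT * fs))
  t <- (-half:half) / fs
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sdT^2))
  w <- w / sqrt(sum(Mod(w)^2))
  list(w = w, half = half)
}

# FFT-based 'same' convolution of the columns of X (time x signals) with a
# centered complex kernel. fftX may be precomputed with padded length N.
convSame <- function(fftX, n, N, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  kern <- complex(length.out = N)
  kern[1:(half + 1L)] <- kernel[(half + 1L):length(kernel)]
  kern[(N - half + 1L):N] <- kernel[1:half]
  fk <- fft(kern)
  out <- mvfft(fftX * fk, inverse = TRUE) / N
  out[seq_len(n), , drop = FALSE]
}

#' Morlet wavelet coefficients
#'
#' Convolves a signal with unit-energy complex Morlet wavelets of the
#' given cycle count at each frequency. Samples within one wavelet
#' half-length of either end are flagged unreliable in the `valid`
#' attribute.
#'
#' @param signal numeric vector, or a time x signals matrix.
#' @param samplingRate Hz.
#' @param frequencies Hz, all within (0, Nyquist).
#' @param nCycles wavelet width in cycles (>= 1).
#' @return complex array `[freq, time]` (or `[freq, time, signal]`) with a
#'   logical `[freq, time]` attribute `valid`.
#' @export
morletCoefficients <- function(signal, samplingRate, frequencies, nCycles = 3) {
  if (nCycles < 1) stop("nCycles must be >= 1", call. = FALSE)
  if (any(frequencies <= 0) || any(frequencies >= samplingRate / 2)) {
    stop("frequencies must lie in (0, Nyquist)", call. = FALSE)
  }
  X <- if (is.matrix(signal)) signal else matrix(signal, ncol = 1L)
  n <- nrow(X)
  ws <- lapply(frequencies, morletWavelet, nCycles = nCycles, fs = samplingRate)
  maxLen <- max(vapply(ws, function(w) length(w$w), integer(1)))
  N <- nextn(n + maxLen, 2)
  fftX <- mvfft(rbind(X, matrix(0, N - n, ncol(X))))
  out <- array(NA_complex_, dim = c(length(frequencies), n, ncol(X)))
  valid <- matrix(TRUE, length(frequencies), n)
  for (i in seq_along(frequencies)) {
    out[i, , ] <- convSame(fftX, n, N, ws[[i]]$w)
    h <- ws[[i]]$half
    if (h >= 1L) valid[i, c(seq_len(min(h, n)),
                            seq.int(max(1L, n - h + 1L), n))] <- FALSE
  }
  if (!is.matrix(signal)) out <- out[, , 1L, drop = TRUE]
  if (length(frequencies) == 1L && !is.matrix(signal)) {
    out <- matrix(out, nrow = 1L)
  }
  attr(out, "valid") <- valid
  out
}

# Superlet order per frequency: linear in frequency between orderMin at
# min(freqs) and orderMax at max(freqs).
superletOrders <- function(frequencies, orderMin, orderMax) {
  if (length(frequencies) == 1L) {
    if (orderMax > orderMin) {
      stop("order interpolation undefined for a single frequency; ",
           "set orderMin == orderMax", call. = FALSE)
    }
    return(orderMin)
  }
  fmin <- min(frequencies); fmax <- max(frequencies)
  orderMin + (orderMax - orderMin) * (frequencies - fmin) / (fmax - fmin)
}

# Weighted geometric mean over wavelet magnitudes for a fractional order o:
# full weight for wavelets 1..floor(o), weight (o - floor(o)) for the
# ceiling wavelet, normalized by o.
superletWeights <- function(o) {
  k <- floor(o)
  w <- rep(1, k)
  if (o > k) w <- c(w, o - k)
  w
}

#' Multiplicative superlet power
#'
#' For each frequency, combines the magnitudes of Morlet responses with
#' cycle counts `i * baseCycles`, `i = 1..ceiling(o)`, by a (weighted)
#' geometric mean, where the order `o` grows linearly with frequency from
#' `orderMin` to `orderMax`. The output is the squared combined magnitude,
#' so an order of 1 reduces exactly to Morlet power at `baseCycles`.
#'
#' @inheritParams morletCoefficients
#' @param baseCycles width of the base wavelet in cycles.
#' @param orderMin,orderMax order range, linearly interpolated across the
#'   frequency grid (`orderMax >= orderMin >= 1`).
#' @return numeric array `[freq, time]` (or `[freq, time, signal]`) of
#'   power, with a logical `valid` attribute marking samples beyond one
#'   half-length of the longest contributing wavelet.
#' @export
superletPower <- function(signal, samplingRate, frequencies, baseCycles = 3,
                          orderMin = 1, orderMax = 20) {
  if (orderMin < 1 || orderMax < orderMin) {
    stop("need orderMax >= orderMin >= 1", call. = FALSE)
  }
  if (any(frequencies <= 0) || any(frequencies >= samplingRate / 2)) {
    stop("frequencies must lie in (0, Nyquist)", call. = FALSE)
  }
  X <- if (is.matrix(signal)) signal else matrix(signal, ncol = 1L)
  n <- nrow(X)
  orders <- superletOrders(frequencies, orderMin, orderMax)
  # longest wavelet actually used: ceiling(order) * baseCycles cycles at
  # each frequency, truncated at 3.5 temporal SDs
  maxLen <- max(2L * ceiling(3.5 * (ceiling(orders) * baseCycles) /
                               (2 * pi * frequencies) * samplingRate)) + 1L
  N <- nextn(n + maxLen, 2)
  fftX <- mvfft(rbind(X, matrix(0, N - n, ncol(X))))
  out <- array(NA_real_, dim = c(length(frequencies), n, ncol(X)))
  valid <- matrix(TRUE, length(frequencies), n)
  for (i in seq_along(frequencies)) {
    wts <- superletWeights(orders[i])
    sumlog <- matrix(0, n, ncol(X))
    half <- 0L
    for (k in seq_along(wts)) {
      wav <- morletWavelet(frequencies[i], k * baseCycles, samplingRate)
      m <- Mod(convSame(fftX, n, N, wav$w))
      sumlog <- sumlog + wts[k] * log(m)
      half <- max(half, wav$half)
    }
    out[i, , ] <- exp(sumlog / sum(wts))^2
    if (half >= 1L) valid[i, c(seq_len(min(half, n)),
                               seq.int(max(1L, n - half + 1L), n))] <- FALSE
  }
  if (!is.matrix(signal)) out <- out[, , 1L, drop = TRUE]
  if (length(frequencies) == 1L && !is.matrix(signal)) {
    out <- matrix(out, nrow = 1L)
  }
  attr(out, "valid") <- valid
  out
}

#' Trial-averaged time-frequency decomposition of epoched data
#'
#' Computes single-trial power with the requested method (multiplicative
#' superlets by default, or plain Morlet), averages across the
#' correct-response trials of every subject x condition cell, and
#' decimates the averaged power to `outputRate` by plain subsampling (the
#' wavelet bandwidth already smooths power in time). Cells with no valid
#' trials are marked missing rather than aborting. Edge samples within one
#' wavelet half-length are flagged in the validity mask.
#'
#' @param epochs an [EpochedData-class].
#' @param method `"superlet"` or `"morlet"`.
#' @param frequencies analysis grid in Hz (default 3-50 Hz in 1 Hz steps).
#' @param baseCycles,orderMin,orderMax superlet parameters; `baseCycles` is
#'   also the Morlet cycle count.
#' @param outputRate decimated sampling rate in Hz; must divide the input
#'   sampling rate.
#' @return a [TimeFrequencyRepresentation-class].
#' @export
tfrEpochs <- function(epochs, method = c("superlet", "morlet"),
                      frequencies = 3:50, baseCycles = 3,
                      orderMin = 1, orderMax = 20, outputRate = 100) {
  method <- match.arg(method)
  fs <- epochs@samplingRate
  dec <- fs / outputRate
  if (abs(dec - round(dec)) > 1e-9) {
    stop("outputRate must divide the sampling rate", call. = FALSE)
  }
  dec <- as.integer(round(dec))
  d <- dim(epochs@samples)
  nS <- d[1]; nC <- d[2]; nR <- d[3]; nCh <- d[4]; nT <- d[5]
  keepT <- seq.int(1L, nT, by = dec)
  power <- array(NA_real_, dim = c(nS, nC, nCh, length(frequencies),
                                   length(keepT)))
  validFull <- NULL
  for (s in seq_len(nS)) {
    for (cc in seq_len(nC)) {
      ok <- which(epochs@accuracy[s, cc, ])
      if (!length(ok)) next
      # time x (trial, channel) matrix: one FFT batch per cell
      X <- matrix(aperm(epochs@samples[s, cc, ok, , , drop = FALSE],
                        c(5, 3, 4, 1, 2)),
                  nrow = nT)
      p <- if (method == "superlet") {
        superletPower(X, fs, frequencies, baseCycles, orderMin, orderMax)
      } else {
        co <- morletCoefficients(X, fs, frequencies, baseCycles)
        v <- attr(co, "valid")
        co <- Mod(co)^2
        attr(co, "valid") <- v
        co
      }
      if (is.null(validFull)) validFull <- attr(p, "valid")
      # average across trials (first block of columns axis)
      dim(p) <- c(length(frequencies), nT, length(ok), nCh)
      avg <- colMeans(aperm(p, c(3, 1, 2, 4)))  # [freq, time, ch]
      power[s, cc, , , ] <- aperm(avg[, keepT, , drop = FALSE], c(3, 1, 2))
    }
  }
  if (is.null(validFull)) validFull <- matrix(TRUE, length(frequencies), nT)
  new("TimeFrequencyRepresentation",
      power = power,
      frequencies = as.numeric(frequencies),
      times = epochs@times[keepT],
      method = method,
      params = list(baseCycles = baseCycles, orderMin = orderMin,
                    orderMax = orderMax),
      outputRate = outputRate,
      valid = validFull[, keepT, drop = FALSE],
      channelNames = epochs@channelNames,
      conditionTable = epochs@conditionTable,
      subjectIds = epochs@subjectIds)
}
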