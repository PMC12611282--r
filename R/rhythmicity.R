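#' Unit phase-increment phasors
#'
#' For an analytic (complex) signal, returns the unit-magnitude phasors of
#' the phase difference between the signal and its copy delayed by
#' `lagSamples`: `z_i = exp(1i * (phi_i - phi_{i - lag}))`. The first
#' `lagSamples` entries, which have no delayed partner, are NA.
#'
#' @param analytic complex vector (analytic signal at one frequency).
#' @param lagSamples integer lag in samples (>= 1, < signal length).
#' @return complex vector of unit phasors (NA where undefined).
#' @export
phaseIncrements <- function(analytic, lagSamples) {
  n <- length(analytic)
  lagSamples <- as.integer(lagSamples)
  if (lagSamples < 1L) stop("lag must be >= 1 sample", call. = FALSE)
  if (lagSamples >= n) stop("lag exceeds signal length", call. = FALSE)
  ph <- Arg(analytic)
  z <- rep(NA_complex_, n)
  z[(lagSamples + 1L):n] <- exp(1i * (ph[(lagSamples + 1L):n] -
                                        ph[1:(n - lagSamples)]))
  z
}

#' Time-resolved phase-autocorrelation function (pACF)
#'
#' Amplitude-independent rhythmicity of an analytic signal at one
#' frequency. For each lag on a grid measured in cycles (converted to
#' samples by rounding; duplicates after rounding are dropped), the unit
#' phase-increment phasors are averaged in a centered moving window of
#' `windowCycles` cycles and the magnitude of that average is taken; the
#' pACF timecourse is the mean of these magnitudes across the lag grid.
#' Values lie in `[0, 1]`: a perfectly stable rhythm gives 1, phase
#' diffusion drives the value toward 0. Timepoints whose window or maximal
#' lag leaves the signal are NA.
#'
#' @param analytic complex analytic-signal vector at `frequency` (e.g. one
#'   row of [morletCoefficients()]).
#' @param samplingRate Hz.
#' @param frequency Hz, the frequency the analytic signal was extracted at.
#' @param lagsCycles lag grid in cycles (default `seq(1, 3, 0.1)`).
#' @param windowCycles centered averaging window length in cycles.
#' @return numeric pACF timecourse in `[0, 1]` (NA at undefined edges).
#' @export
pacfTimeResolved <- function(analytic, samplingRate, frequency,
                             lagsCycles = seq(1, 3, by = 0.1),
                             windowCycles = 2.5) {
  n <- length(analytic)
  lagSamp <- unique(pmax(1L, as.integer(round(lagsCycles * samplingRate /
                                                frequency))))
  w <- as.integer(round(windowCycles * samplingRate / frequency))
  if (w < 3L) stop("window shorter than 3 samples", call. = FALSE)
  if (max(lagSamp) >= n) stop("maximal lag exceeds signal length", call. = FALSE)
  half <- w %/% 2L
  acc <- numeric(n)
  for (l in lagSamp) {
    z <- phaseIncrements(analytic, l)
    zre <- Re(z); zim <- Im(z)
    zre[is.na(zre)] <- 0; zim[is.na(zim)] <- 0
    mre <- movingAverage(zre, w)
    mim <- movingAverage(zim, w)
    acc <- acc + sqrt(mre^2 + mim^2)
  }
  out <- acc / length(lagSamp)
  # invalidate timepoints whose window reaches into the lag-undefined or
  # out-of-signal region
  bad <- seq_len(min(n, max(lagSamp) + half))
  bad <- c(bad, seq.int(max(1L, n - half + 1L), n))
  out[bad] <- NA_real_
  pmin(out, 1)
}

#' Rhythmicity map of epoched data
#'
#' Computes the time-resolved pACF for every subject x condition x channel
#' cell and frequency. The analytic signal is obtained by 3-cycle complex
#' Morlet convolution (superlets are not used here: mixing wavelet widths
#' distorts phase autocorrelation). Single-trial pACF timecourses are
#' averaged across the correct-response trials of each cell, then
#' decimated to `outputRate`.
#'
#' @param epochs an [EpochedData-class].
#' @param frequencies Hz grid.
#' @param lagsCycles,windowCycles see [pacfTimeResolved()].
#' @param nCycles Morlet cycles for the analytic signal.
#' @param outputRate decimated output rate (Hz); must divide the sampling
#'   rate.
#' @return a [RhythmicityMap-class].
#' @export
pacfEpochs <- function(epochs, frequencies = 3:50,
                       lagsCycles = seq(1, 3, by = 0.1),
                       windowCycles = 2.5, nCycles = 3, outputRate = 100) {
  fs <- epochs@samplingRate
  dec <- fs / outputRate
  if (abs(dec - round(dec)) > 1e-9) {
    stop("outputRate must divide the sampling rate", call. = FALSE)
  }
  dec <- as.integer(round(dec))
  d <- dim(epochs@samples)
  nS <- d[1]; nC <- d[2]; nCh <- d[4]; nT <- d[5]
  keepT <- seq.int(1L, nT, by = dec)
  out <- array(NA_real_, dim = c(nS, nC, nCh, length(frequencies),
                                 length(keepT)))
  for (s in seq_len(nS)) for (cc in seq_len(nC)) {
    ok <- which(epochs@accuracy[s, cc, ])
    if (!length(ok)) next
    X <- matrix(aperm(epochs@samples[s, cc, ok, , , drop = FALSE],
                      c(5, 3, 4, 1, 2)), nrow = nT)
    co <- morletCoefficients(X, fs, frequencies, nCycles)
    for (fi in seq_along(frequencies)) {
      pac <- matrix(NA_real_, nT, ncol(X))
      for (j in seq_len(ncol(X))) {
        pac[, j] <- pacfTimeResolved(co[fi, , j], fs, frequencies[fi],
                                     lagsCycles, windowCycles)
      }
      dim(pac) <- c(nT, length(ok), nCh)
      avg <- apply(pac, c(1, 3), mean)  # average over trials
      out[s, cc, , fi, ] <- t(avg[keepT, , drop = FALSE])
    }
  }
  new("RhythmicityMap",
      pacf = out,
      frequencies = as.numeric(frequencies),
      times = epochs@times[keepT],
      lagsCycles = lagsCycles,
      windowCycles = windowCycles,
      channelNames = epochs@channelNames,
      conditionTable = epochs@conditionTable,
      subjectIds = epochs@subjectIds)
}
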