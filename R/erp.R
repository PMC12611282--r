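#' Compute event-related potentials
#'
#' Arithmetic mean over the correct-response trials of every subject x
#' condition cell. Empty cells are left NA (missing, not an error).
#'
#' @param epochs an [EpochedData-class].
#' @return an [ERPData-class].
#' @export
computeERP <- function(epochs) {
  d <- dim(epochs@samples)
  nS <- d[1]; nC <- d[2]; nCh <- d[4]; nT <- d[5]
  avg <- array(NA_real_, dim = c(nS, nC, nCh, nT))
  nTrials <- matrix(0L, nS, nC)
  for (s in seq_len(nS)) for (cc in seq_len(nC)) {
    ok <- which(epochs@accuracy[s, cc, ])
    nTrials[s, cc] <- length(ok)
    if (!length(ok)) next
    x <- array(epochs@samples[s, cc, ok, , ], dim = c(length(ok), nCh, nT))
    avg[s, cc, , ] <- colMeans(x)
  }
  new("ERPData", average = avg, times = epochs@times, nTrials = nTrials,
      channelNames = epochs@channelNames,
      conditionTable = epochs@conditionTable,
      subjectIds = epochs@subjectIds)
}

#' Subtract ERPs from single-trial data
#'
#' Removes each cell's average waveform from every trial of that cell, so
#' the trial mean of the output is exactly zero per cell. Removing the
#' phase-locked (evoked) part before time-frequency decomposition leaves
#' induced activity, which is how evoked transients are prevented from
#' contaminating aperiodic estimates.
#'
#' @param epochs an [EpochedData-class].
#' @param erp the matching [ERPData-class] (computed if omitted).
#' @return an [EpochedData-class] with ERP-subtracted samples.
#' @export
subtractERP <- function(epochs, erp = NULL) {
  if (is.null(erp)) erp <- computeERP(epochs)
  if (!isTRUE(all.equal(erp@times, epochs@times)) ||
      !identical(dim(erp@average)[1:2], dim(epochs@samples)[1:2]) ||
      !identical(dim(erp@average)[3], dim(epochs@samples)[4])) {
    stop("ERP axes do not match the epochs", call. = FALSE)
  }
  out <- epochs@samples
  d <- dim(out)
  for (s in seq_len(d[1])) for (cc in seq_len(d[2])) {
    e <- erp@average[s, cc, , ]
    if (all(is.na(e))) next
    ok <- which(epochs@accuracy[s, cc, ])
    for (r in ok) out[s, cc, r, , ] <- out[s, cc, r, , ] - e
  }
  initialize(epochs, samples = out)
}

#' Re-anchor ERPs to the response
#'
#' Shifts each subject x condition average so that time 0 is the cell's
#' median reaction time, by a whole-sample shift (nearest sample, no
#' interpolation). Samples shifted in from outside the epoch are NA.
#'
#' @param erp an [ERPData-class].
#' @param epochs the [EpochedData-class] supplying reaction times.
#' @return an [ERPData-class] with response-locked averages.
#' @export
responseLockERP <- function(erp, epochs) {
  d <- dim(erp@average)
  out <- array(NA_real_, dim = d)
  dt <- 1 / epochs@samplingRate
  for (s in seq_len(d[1])) for (cc in seq_len(d[2])) {
    rt <- median(epochs@reactionTimes[s, cc, ], na.rm = TRUE)
    if (!is.finite(rt)) next
    shift <- as.integer(round(rt / dt))
    nT <- d[4]
    src <- seq_len(nT) + shift
    keep <- src >= 1L & src <= nT
    out[s, cc, , which(keep)] <- erp@average[s, cc, , src[keep]]
  }
  initialize(erp, average = out)
}

#' ERP amplitude as a predictor of aperiodic activity
#'
#' Delegates to [massUnivariateR2()] with the ERP amplitude as the fixed
#' predictor of the aperiodic exponent map per channel-timepoint, with
#' subject and condition random intercepts. Quantifies how much of the
#' aperiodic dynamics could be explained by evoked potentials.
#'
#' @param erp an [ERPData-class].
#' @param exponentMap array `[subject, condition, channel, time]` of
#'   aperiodic exponents on a time axis contained in the ERP's.
#' @param times time axis of `exponentMap` (seconds).
#' @return a [StatMap-class] of signed marginal R-squared.
#' @export
erpAperiodicR2 <- function(erp, exponentMap, times) {
  sel <- nearestIndex(erp@times, times)
  pred <- erp@average[, , , sel, drop = FALSE]
  massUnivariateR2(exponentMap, pred,
                   channelNames = erp@channelNames,
                   times = times)
}
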