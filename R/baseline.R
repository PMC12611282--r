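#' Baseline-correct a time-frequency representation
#'
#' Applies one of four baseline-correction variants to trial-averaged
#' power, per subject x condition x channel x frequency, using the
#' arithmetic mean of power inside a pre-stimulus window as the baseline
#' statistic B:
#' \describe{
#'   \item{decibel}{`10 * log10(data / B)`}
#'   \item{relative_change}{`(data - B) / B`}
#'   \item{normalized_change}{`(data - B) / (data + B)`}
#'   \item{absolute_change}{`data - B`}
#' }
#' Each cell is corrected with its own baseline (no grand baseline).
#'
#' @param tfr a [TimeFrequencyRepresentation-class].
#' @param method one of `"decibel"`, `"relative_change"`,
#'   `"normalized_change"`, `"absolute_change"`.
#' @param window numeric length-2, baseline window in seconds with
#'   `start < end <= 0`; conventional choices are `c(-0.5, -0.2)`,
#'   `c(-0.3, 0)` and `c(-0.5, 0)`.
#' @return array shaped like `tfrPower(tfr)` of corrected values.
#' @export
applyBaseline <- function(tfr,
                          method = c("decibel", "relative_change",
                                     "normalized_change", "absolute_change"),
                          window = c(-0.5, -0.2)) {
  method <- match.arg(method)
  if (length(window) != 2 || !(window[1] < window[2]) || window[2] > 0) {
    stop("baseline window must satisfy start < end <= 0", call. = FALSE)
  }
  times <- tfr@times
  sel <- which(times >= window[1] & times <= window[2])
  if (length(sel) < 1L) {
    stop("baseline window lies outside the epoch", call. = FALSE)
  }
  if (!all(tfr@valid[, sel])) {
    stop("baseline window overlaps the edge-invalid region", call. = FALSE)
  }
  p <- tfr@power
  d <- dim(p)
  # baseline mean over window timepoints: [s, c, ch, f]
  B <- apply(p[, , , , sel, drop = FALSE], 1:4, mean)
  if (method %in% c("decibel", "relative_change")) {
    bad <- which(B <= 0 & is.finite(B), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-positive baseline under a ratio method (channel %s, %.1f Hz)",
        tfr@channelNames[bad[1, 3]], tfr@frequencies[bad[1, 4]]),
        call. = FALSE)
    }
  }
  Bfull <- array(B, dim = d)  # recycle over the trailing time dimension
  out <- switch(method,
    decibel = 10 * log10(p / Bfull),
    relative_change = (p - Bfull) / Bfull,
    normalized_change = (p - Bfull) / (p + Bfull),
    absolute_change = p - Bfull
  )
  dimnames(out) <- dimnames(p)
  out
}
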