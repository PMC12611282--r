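# Shared fixtures, built lazily and cached for the duration of the run.

.fixtureCache <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) assign(name, builder(), .fixtureCache)
  .fixtureCache[[name]]
}

# One condition pair (nontarget/target), small but realistic epochs.
smallConditionTable <- function() {
  expand.grid(modality = "verbal", load = "2back",
              stimulus = c("nontarget", "target"), stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Yekutieli step-up, straight from the definition.
bruteForceBY <- function(p, q = 0.05) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  thr <- seq_len(m) * q / (m * cm)
  k <- which(ps <= thr)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Brute-force cluster rule: point kept iff >= minTime consecutive
# significant timepoints through it at its channel, or >= minChannels
# channels significant at its timepoint.
bruteForceCluster <- function(mask, minTime = 3L, minChannels = 3L) {
  out <- mask & FALSE
  nCh <- nrow(mask); nT <- ncol(mask)
  for (ch in seq_len(nCh)) for (ti in seq_len(nT)) {
    if (!mask[ch, ti]) next
    if (sum(mask[, ti]) >= minChannels) { out[ch, ti] <- TRUE; next }
    run <- 1L
    j <- ti - 1L
    while (j >= 1L && mask[ch, j]) { run <- run + 1L; j <- j - 1L }
    j <- ti + 1L
    while (j <= nT && mask[ch, j]) { run <- run + 1L; j <- j + 1L }
    if (run >= minTime) out[ch, ti] <- TRUE
  }
  out
}

# Welch + log-log least squares: the independent slope oracle for
# time-domain aperiodic signals.
fittedLogLogSlope <- function(x, fs, fmin = 2, fmax = fs / 5) {
  p <- specsift:::welchPsd(x, fs)
  sel <- p$freq >= fmin & p$freq <= fmax
  unname(coef(lm(log10(p$psd[sel]) ~ log10(p$freq[sel])))[2])
}
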