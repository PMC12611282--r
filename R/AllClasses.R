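#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Ground-truth simulation specification
#'
#' Describes a fully synthetic multi-subject, multi-condition epoched EEG
#' dataset with known periodic and aperiodic structure: a 1/f background
#' whose exponent and offset vary in time (Gaussian-in-time "events"),
#' sinusoidal oscillations with post-stimulus amplitude suppression, an
#' additive phase-locked ERP template, white sensor noise, between-subject
#' variation of the aperiodic baseline, and ex-Gaussian reaction times.
#'
#' @slot nSubjects number of simulated subjects.
#' @slot trialsPerCondition trials per subject and condition cell.
#' @slot conditionTable data.frame with columns `modality`, `load`,
#'   `stimulus`; one row per condition cell.
#' @slot channelNames channel labels.
#' @slot channelGroups named list of per-channel weight vectors in `[0, 1]`
#'   (e.g. `frontal`, `parietal`, `occipital`).
#' @slot samplingRate sampling rate in Hz.
#' @slot epochWindow numeric length-2, epoch start/end in seconds with the
#'   stimulus at 0 (start < 0 < end).
#' @slot aperiodicOffset baseline offset b0, log10-power units.
#' @slot aperiodicExponent baseline exponent chi0 (>= 0).
#' @slot exponentEvents list of events, each a list with `latency` (s),
#'   `width` (s), `amplitude` (delta chi), `group` (channel-group name),
#'   optionally `conditionMod` (named per-condition multipliers) and
#'   `pivotHz` (rotation frequency, default 20 Hz: the offset co-varies as
#'   `delta-b = delta-chi * log10(pivotHz)` so the spectrum rotates about
#'   the pivot; 0 gives a pure tilt with fixed offset).
#' @slot oscillations list of oscillations, each a list with `freq` (Hz),
#'   `amplitude` (signal units), `preLevel`, `suppressionOnset` (s),
#'   `suppressionDuration` (s), `suppressionDepth` in `[0, 1]`, `group`,
#'   and optionally `conditionMod`.
#' @slot erpTemplate list with `amplitude`, `latency` (s), `width` (s),
#'   `group`, or NULL for no ERP.
#' @slot subjectRandomSD between-subject SD applied to b0 and chi0.
#' @slot sensorNoiseSD additive white-noise SD (signal units).
#' @slot rtModel data.frame with columns `mu`, `sigma`, `tau` (seconds), one
#'   row per condition (recycled if a single row).
#' @slot seed master integer seed.
#' @export
setClass("GroundTruthSpec",
  representation(
    nSubjects = "integer",
    trialsPerCondition = "integer",
    conditionTable = "data.frame",
    channelNames = "character",
    channelGroups = "list",
    samplingRate = "numeric",
    epochWindow = "numeric",
    aperiodicOffset = "numeric",
    aperiodicExponent = "numeric",
    exponentEvents = "list",
    oscillations = "list",
    erpTemplate = "listOrNULL",
    subjectRandomSD = "numeric",
    sensorNoiseSD = "numeric",
    rtModel = "data.frame",
    seed = "integer"
  )
)

setValidity("GroundTruthSpec", function(object) {
  msg <- character(0)
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (length(object@epochWindow) != 2 ||
      !(object@epochWindow[1] < 0 && object@epochWindow[2] > 0)) {
    msg <- c(msg, "epochWindow must satisfy start < 0 < end")
  }
  if (object@aperiodicExponent < 0) msg <- c(msg, "aperiodicExponent must be >= 0")
  if (object@nSubjects < 1L || object@trialsPerCondition < 1L) {
    msg <- c(msg, "subject and trial counts must be >= 1")
  }
  lbl <- do.call(paste, c(object@conditionTable, sep = "|"))
  if (anyDuplicated(lbl)) msg <- c(msg, "condition labels must be unique")
  for (osc in object@oscillations) {
    if (osc$suppressionDepth < 0 || osc$suppressionDepth > 1) {
      msg <- c(msg, "suppression depth must be in [0, 1]")
    }
  }
  if (any(object@rtModel$mu <= 0) || any(object@rtModel$sigma <= 0) ||
      any(object@rtModel$tau <= 0)) {
    msg <- c(msg, "rt model parameters mu, sigma, tau must be > 0")
  }
  nm <- unlist(lapply(object@exponentEvents, `[[`, "group"))
  nm <- c(nm, unlist(lapply(object@oscillations, `[[`, "group")))
  if (!is.null(object@erpTemplate)) nm <- c(nm, object@erpTemplate$group)
  bad <- setdiff(nm, names(object@channelGroups))
  if (length(bad)) msg <- c(msg, paste("unknown channel group:", bad[1]))
  for (g in object@channelGroups) {
    if (length(g) != length(object@channelNames) ||
        any(g < 0) || any(g > 1)) {
      msg <- c(msg, "channel-group weights must be per-channel values in [0, 1]")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Epoched multi-subject EEG data
#'
#' Single-trial epoched EEG with subject/condition structure, reaction times
#' and accuracy flags. Samples are stored as a 5-D array
#' `subject x condition x trial x channel x time`; the time axis is in
#' seconds with the stimulus at 0.
#'
#' @slot samples 5-D numeric array `[subject, condition, trial, channel, time]`.
#' @slot samplingRate Hz.
#' @slot times time axis (s), strictly increasing and uniform.
#' @slot channelNames channel labels.
#' @slot conditionTable data.frame (`modality`, `load`, `stimulus`).
#' @slot reactionTimes array `[subject, condition, trial]` (s, NA if missing).
#' @slot accuracy logical array `[subject, condition, trial]`.
#' @slot subjectIds subject labels.
#' @export
setClass("EpochedData",
  representation(
    samples = "array",
    samplingRate = "numeric",
    times = "numeric",
    channelNames = "character",
    conditionTable = "data.frame",
    reactionTimes = "array",
    accuracy = "array",
    subjectIds = "character"
  )
)

setValidity("EpochedData", function(object) {
  msg <- character(0)
  d <- dim(object@samples)
  if (length(d) != 5) msg <- c(msg, "samples must be a 5-D array")
  if (!all(is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (!isUniformAxis(object@times)) {
    msg <- c(msg, "time axis must be uniform and increasing")
  }
  if (length(d) == 5) {
    if (d[5] != length(object@times)) msg <- c(msg, "time axis length mismatch")
    if (d[4] != length(object@channelNames)) msg <- c(msg, "channel mismatch")
    if (d[2] != nrow(object@conditionTable)) msg <- c(msg, "condition mismatch")
    if (d[1] != length(object@subjectIds)) msg <- c(msg, "subject mismatch")
    if (!all(dim(object@reactionTimes) == d[1:3])) {
      msg <- c(msg, "reactionTimes dims must match samples")
    }
  }
  rt <- object@reactionTimes
  if (any(rt[!is.na(rt)] <= 0)) msg <- c(msg, "reaction times must be positive")
  if (length(msg)) msg else TRUE
})

#' Trial-averaged time-frequency representation
#'
#' Power over `subject x condition x channel x frequency x time` in linear
#' power units, with the decomposition method, its parameters, and a
#' per-frequency validity mask marking samples within one wavelet
#' half-length of the epoch edges.
#'
#' @slot power 5-D non-negative array `[subject, condition, channel, freq, time]`.
#' @slot frequencies Hz, strictly increasing.
#' @slot times seconds, uniform at `outputRate`.
#' @slot method `"morlet"` or `"superlet"`.
#' @slot params list of method parameters.
#' @slot outputRate Hz after decimation.
#' @slot valid logical matrix `[freq, time]`; FALSE within edge regions.
#' @slot channelNames,conditionTable,subjectIds metadata carried from the epochs.
#' @export
setClass("TimeFrequencyRepresentation",
  representation(
    power = "array",
    frequencies = "numeric",
    times = "numeric",
    method = "character",
    params = "list",
    outputRate = "numeric",
    valid = "matrix",
    channelNames = "character",
    conditionTable = "data.frame",
    subjectIds = "character"
  )
)

setValidity("TimeFrequencyRepresentation", function(object) {
  msg <- character(0)
  d <- dim(object@power)
  if (length(d) != 5) msg <- c(msg, "power must be a 5-D array")
  if (any(object@power[is.finite(object@power)] < 0)) {
    msg <- c(msg, "power must be non-negative")
  }
  if (is.unsorted(object@frequencies, strictly = TRUE)) {
    msg <- c(msg, "frequencies must be strictly increasing")
  }
  if (!isUniformAxis(object@times)) msg <- c(msg, "times must be uniform")
  if (length(d) == 5 &&
      !(d[4] == length(object@frequencies) && d[5] == length(object@times))) {
    msg <- c(msg, "frequency/time axis mismatch")
  }
  if (length(msg)) msg else TRUE
})

#' Per-timepoint spectral parameterization of a TFR
#'
#' Maps of the aperiodic offset and exponent, the reconstructed periodic
#' (peaks-only) log10-power, and fit metrics, estimated for every channel
#' and timepoint inside the analysis window.
#'
#' @slot offset,exponent,rSquared,mae,nPeaks arrays `[subject, condition, channel, time]`.
#' @slot periodic array `[subject, condition, channel, freq, time]`,
#'   log10-power of the reconstructed peaks, non-negative by construction.
#' @slot frequencies Hz. @slot times seconds (analysis window only).
#' @slot window numeric length-2, analysis window (s).
#' @slot settings spectral-parameterization settings used.
#' @slot channelNames,conditionTable,subjectIds metadata.
#' @export
setClass("ParameterizedTFR",
  representation(
    offset = "array",
    exponent = "array",
    rSquared = "array",
    mae = "array",
    nPeaks = "array",
    periodic = "array",
    frequencies = "numeric",
    times = "numeric",
    window = "numeric",
    settings = "list",
    channelNames = "character",
    conditionTable = "data.frame",
    subjectIds = "character"
  )
)

setValidity("ParameterizedTFR", function(object) {
  msg <- character(0)
  p <- object@periodic
  if (any(p[is.finite(p)] < 0)) msg <- c(msg, "periodic power must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Phase-autocorrelation rhythmicity map
#'
#' Amplitude-independent rhythmicity values in `[0, 1]` over
#' `subject x condition x channel x frequency x time`, from the temporal
#' stability of phase increments at lags of 1-3 cycles.
#'
#' @slot pacf array `[subject, condition, channel, freq, time]` in `[0, 1]`
#'   (NA where the window or maximal lag leaves the valid epoch region).
#' @slot frequencies Hz. @slot times seconds.
#' @slot lagsCycles lag grid in cycles. @slot windowCycles window length in cycles.
#' @slot channelNames,conditionTable,subjectIds metadata.
#' @export
setClass("RhythmicityMap",
  representation(
    pacf = "array",
    frequencies = "numeric",
    times = "numeric",
    lagsCycles = "numeric",
    windowCycles = "numeric",
    channelNames = "character",
    conditionTable = "data.frame",
    subjectIds = "character"
  )
)

setValidity("RhythmicityMap", function(object) {
  v <- object@pacf[is.finite(object@pacf)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9)) {
    "pacf values must lie in [0, 1]"
  } else TRUE
})

#' Mass-univariate statistics map for one model term
#'
#' Per channel(-frequency)-timepoint coefficient, signed marginal
#' R-squared, p value, FDR-significance and cluster-filtered significance
#' for one fixed-effect term of the mixed model.
#'
#' @slot term model term name.
#' @slot coefficient,rSquared,p arrays `[channel, freq, time]` (freq may be 1).
#' @slot fdrMask,clusterMask logical arrays of the same shape; the cluster
#'   mask is always a subset of the FDR mask.
#' @slot channelNames,frequencies,times axis metadata.
#' @export
setClass("StatMap",
  representation(
    term = "character",
    coefficient = "array",
    rSquared = "array",
    p = "array",
    fdrMask = "array",
    clusterMask = "array",
    channelNames = "character",
    frequencies = "numeric",
    times = "numeric"
  )
)

setValidity("StatMap", function(object) {
  ok <- !(object@clusterMask & !object@fdrMask)
  if (!all(ok, na.rm = TRUE)) "clusterMask must be a subset of fdrMask" else TRUE
})

#' Event-related potentials
#'
#' Trial-averaged waveforms per subject, condition and channel, with the
#' trial counts that entered each average.
#'
#' @slot average array `[subject, condition, channel, time]`.
#' @slot times seconds. @slot nTrials matrix `[subject, condition]`.
#' @slot channelNames,conditionTable,subjectIds metadata.
#' @export
setClass("ERPData",
  representation(
    average = "array",
    times = "numeric",
    nTrials = "matrix",
    channelNames = "character",
    conditionTable = "data.frame",
    subjectIds = "character"
  )
)

setValidity("ERPData", function(object) {
  d <- dim(object@average)
  if (length(d) != 4 || d[4] != length(object@times)) {
    "average must be [subject, condition, channel, time] matching times"
  } else TRUE
})

#' Spectral model of a single power spectrum
#'
#' Aperiodic parameters (offset, exponent; knee fixed at 0), Gaussian peak
#' parameters, and fit metrics for one power spectrum in semi-log space.
#'
#' @slot aperiodic named numeric `c(offset, exponent)`.
#' @slot peaks matrix with columns `cf` (Hz), `pw` (log10-power above the
#'   aperiodic fit), `sd` (Hz); reported bandwidth is `2 * sd`.
#' @slot rSquared fit R-squared in log space. @slot mae mean absolute error
#'   (log10-power units). @slot freqRange fitted range (Hz).
#' @slot flags character vector of fit warnings (empty when clean).
#' @export
setClass("SpectralModel",
  representation(
    aperiodic = "numeric",
    peaks = "matrix",
    rSquared = "numeric",
    mae = "numeric",
    freqRange = "numeric",
    flags = "character"
  )
)

setValidity("SpectralModel", function(object) {
  msg <- character(0)
  if (length(object@rSquared) && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared must be <= 1")
  if (length(object@mae) && is.finite(object@mae) && object@mae < 0) {
    msg <- c(msg, "mae must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood linear mixed model fit
#'
#' Random-intercept model fit by maximum likelihood, with one or two
#' (crossed) grouping factors. Holds fixed effects with their covariance,
#' variance components, the fixed-effects variance used by the marginal
#' R-squared, and the design needed for Satterthwaite inference.
#'
#' @slot beta named fixed-effect estimates. @slot vcovBeta their covariance.
#' @slot varComps named variance components (one per grouping factor, plus
#'   `residual`). @slot sigmaF2 variance of the fixed-effect predictions.
#' @slot logLik maximized log-likelihood. @slot nobs rows used.
#' @slot model list with `y`, `X`, and `groups` (list of factors) for
#'   downstream inference. @slot converged logical.
#' @export
setClass("LMMFit",
  representation(
    beta = "numeric",
    vcovBeta = "matrix",
    varComps = "numeric",
    sigmaF2 = "numeric",
    logLik = "numeric",
    nobs = "integer",
    model = "list",
    converged = "logical"
  )
)

setValidity("LMMFit", function(object) {
  if (any(object@varComps < -1e-10) || object@sigmaF2 < -1e-10) {
    "variance components must be non-negative"
  } else TRUE
})
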