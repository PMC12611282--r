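#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. `tfrPower`,
#' `periodicPower`, `exponentMap`, `offsetMap` and `rhythmicityValues`
#' return the underlying arrays with dimension names attached; `frequencies`
#' and `timeAxis` return the corresponding axes in Hz and seconds.
#'
#' @param object one of the package's S4 containers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(object) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("conditionTable", function(object) standardGeneric("conditionTable"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("tfrPower", function(object) standardGeneric("tfrPower"))

#' @rdname accessors
#' @export
setGeneric("periodicPower", function(object) standardGeneric("periodicPower"))

#' @rdname accessors
#' @export
setGeneric("exponentMap", function(object) standardGeneric("exponentMap"))

#' @rdname accessors
#' @export
setGeneric("offsetMap", function(object) standardGeneric("offsetMap"))

#' @rdname accessors
#' @export
setGeneric("rhythmicityValues", function(object) standardGeneric("rhythmicityValues"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("aperiodicParams", function(object) standardGeneric("aperiodicParams"))

#' @rdname accessors
#' @export
setGeneric("peakParams", function(object) standardGeneric("peakParams"))

setMethod("frequencies", "TimeFrequencyRepresentation", function(object) object@frequencies)
setMethod("frequencies", "ParameterizedTFR", function(object) object@frequencies)
setMethod("frequencies", "RhythmicityMap", function(object) object@frequencies)
setMethod("frequencies", "StatMap", function(object) object@frequencies)

setMethod("timeAxis", "EpochedData", function(object) object@times)
setMethod("timeAxis", "TimeFrequencyRepresentation", function(object) object@times)
setMethod("timeAxis", "ParameterizedTFR", function(object) object@times)
setMethod("timeAxis", "RhythmicityMap", function(object) object@times)
setMethod("timeAxis", "ERPData", function(object) object@times)
setMethod("timeAxis", "StatMap", function(object) object@times)

setMethod("channelNames", "EpochedData", function(object) object@channelNames)
setMethod("channelNames", "TimeFrequencyRepresentation", function(object) object@channelNames)
setMethod("channelNames", "ParameterizedTFR", function(object) object@channelNames)
setMethod("channelNames", "RhythmicityMap", function(object) object@channelNames)
setMethod("channelNames", "ERPData", function(object) object@channelNames)
setMethod("channelNames", "StatMap", function(object) object@channelNames)
setMethod("channelNames", "GroundTruthSpec", function(object) object@channelNames)

setMethod("conditionTable", "EpochedData", function(object) object@conditionTable)
setMethod("conditionTable", "TimeFrequencyRepresentation", function(object) object@conditionTable)
setMethod("conditionTable", "ParameterizedTFR", function(object) object@conditionTable)
setMethod("conditionTable", "RhythmicityMap", function(object) object@conditionTable)
setMethod("conditionTable", "ERPData", function(object) object@conditionTable)
setMethod("conditionTable", "GroundTruthSpec", function(object) object@conditionTable)

setMethod("subjectIds", "EpochedData", function(object) object@subjectIds)
setMethod("subjectIds", "TimeFrequencyRepresentation", function(object) object@subjectIds)
setMethod("subjectIds", "ParameterizedTFR", function(object) object@subjectIds)

setMethod("samplingRate", "EpochedData", function(object) object@samplingRate)
setMethod("samplingRate", "GroundTruthSpec", function(object) object@samplingRate)

setMethod("tfrPower", "TimeFrequencyRepresentation", function(object) object@power)
setMethod("periodicPower", "ParameterizedTFR", function(object) object@periodic)
setMethod("exponentMap", "ParameterizedTFR", function(object) object@exponent)
setMethod("offsetMap", "ParameterizedTFR", function(object) object@offset)
setMethod("rhythmicityValues", "RhythmicityMap", function(object) object@pacf)

setMethod("aperiodicParams", "SpectralModel", function(object) object@aperiodic)
setMethod("peakParams", "SpectralModel", function(object) object@peaks)

setMethod("show", "GroundTruthSpec", function(object) {
  cat("GroundTruthSpec:", object@nSubjects, "subjects x",
      nrow(object@conditionTable), "conditions x",
      object@trialsPerCondition, "trials x",
      length(object@channelNames), "channels\n")
  cat("  fs =", object@samplingRate, "Hz, epoch",
      object@epochWindow[1], "to", object@epochWindow[2], "s\n")
  cat("  aperiodic baseline: offset", object@aperiodicOffset,
      ", exponent", object@aperiodicExponent, "\n")
  cat("  ", length(object@exponentEvents), "exponent event(s), ",
      length(object@oscillations), "oscillation(s), ERP ",
      if (is.null(object@erpTemplate)) "absent" else "present", "\n", sep = "")
})

setMethod("show", "EpochedData", function(object) {
  d <- dim(object@samples)
  cat("EpochedData:", d[1], "subjects x", d[2], "conditions x", d[3],
      "trials x", d[4], "channels x", d[5], "samples\n")
  cat("  fs =", object@samplingRate, "Hz, time",
      round(min(object@times), 3), "to", round(max(object@times), 3), "s\n")
})

setMethod("show", "TimeFrequencyRepresentation", function(object) {
  d <- dim(object@power)
  cat("TimeFrequencyRepresentation (", object@method, "): ", d[1], " x ", d[2],
      " x ", d[3], " channels x ", d[4], " freqs x ", d[5], " times\n", sep = "")
  cat("  ", min(object@frequencies), "-", max(object@frequencies),
      " Hz, output rate ", object@outputRate, " Hz\n", sep = "")
})

setMethod("show", "ParameterizedTFR", function(object) {
  d <- dim(object@exponent)
  cat("ParameterizedTFR:", d[1], "subjects x", d[2], "conditions x", d[3],
      "channels x", d[4], "timepoints\n")
  cat("  window", object@window[1], "to", object@window[2], "s;",
      sum(!is.finite(object@exponent)), "failed fits\n")
})

setMethod("show", "RhythmicityMap", function(object) {
  d <- dim(object@pacf)
  cat("RhythmicityMap:", d[1], "x", d[2], "x", d[3], "channels x", d[4],
      "freqs x", d[5], "times; lags",
      min(object@lagsCycles), "-", max(object@lagsCycles), "cycles\n")
})

setMethod("show", "StatMap", function(object) {
  cat("StatMap for term '", object@term, "': ",
      sum(object@fdrMask, na.rm = TRUE), " FDR-significant, ",
      sum(object@clusterMask, na.rm = TRUE),
      " after cluster filtering\n", sep = "")
})

setMethod("show", "ERPData", function(object) {
  d <- dim(object@average)
  cat("ERPData:", d[1], "subjects x", d[2], "conditions x", d[3],
      "channels x", d[4], "samples\n")
})

setMethod("show", "SpectralModel", function(object) {
  cat("SpectralModel: offset", round(object@aperiodic[1], 3),
      ", exponent", round(object@aperiodic[2], 3), ",",
      nrow(object@peaks), "peak(s)\n")
  if (nrow(object@peaks)) {
    for (i in seq_len(nrow(object@peaks))) {
      cat(sprintf("  peak %d: cf = %.2f Hz, power = %.3f, bw = %.2f Hz\n",
                  i, object@peaks[i, "cf"], object@peaks[i, "pw"],
                  2 * object@peaks[i, "sd"]))
    }
  }
  cat(sprintf("  R2 = %.4f, MAE = %.4f\n", object@rSquared, object@mae))
})

setMethod("show", "LMMFit", function(object) {
  cat("LMMFit (ML):", length(object@beta), "fixed effects,",
      object@nobs, "rows\n")
  print(round(object@beta, 4))
  cat("  variance components:",
      paste(names(object@varComps), round(object@varComps, 4),
            sep = " = ", collapse = ", "), "\n")
})
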