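CONTAINER_SCHEMA <- c(major = 1L, minor = 0L)

#' Write an analysis object to the pipeline container
#'
#' Serializes any of the package's S4 containers (or a results bundle
#' list) into a single self-describing container file with an embedded
#' schema version and manifest, so a run can be restarted from disk.
#' Round-trips are lossless for arrays and metadata.
#'
#' @param obj object to store.
#' @param path destination file path.
#' @param extra optional named list of extra groups stored alongside the
#'   payload (preserved verbatim on read).
#' @return the path, invisibly.
#' @export
writeContainer <- function(obj, path, extra = list()) {
  payload <- list(
    schema = as.list(CONTAINER_SCHEMA),
    class = class(obj)[1],
    manifest = list(
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      package = "specsift",
      version = as.character(utils::packageVersion("specsift"))
    ),
    payload = obj
  )
  if (length(extra)) payload[names(extra)] <- extra
  saveRDS(payload, path)
  invisible(path)
}

#' Read an object back from the pipeline container
#'
#' Validates the schema version (same major version required; newer minor
#' versions are tolerated and extra groups preserved in the `extras`
#' attribute) and returns the stored object. Truncated or foreign files
#' produce an explicit schema error rather than a crash.
#'
#' @param path container file path.
#' @return the stored object, with attributes `manifest` and `extras`.
#' @export
readContainer <- function(path) {
  raw <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) NULL)
  if (is.null(raw) || !is.list(raw) || is.null(raw$schema)) {
    stop("not a valid container file (unreadable or truncated): ", path,
         call. = FALSE)
  }
  sv <- raw$schema
  if (!identical(as.integer(sv$major), CONTAINER_SCHEMA[["major"]])) {
    stop(sprintf("unsupported container schema %s.%s (expected %d.x)",
                 sv$major, sv$minor, CONTAINER_SCHEMA[["major"]]),
         call. = FALSE)
  }
  obj <- raw$payload
  attr(obj, "manifest") <- raw$manifest
  extras <- raw[setdiff(names(raw), c("schema", "class", "manifest",
                                      "payload"))]
  if (length(extras)) attr(obj, "extras") <- extras
  obj
}

#' Assemble and validate an analysis configuration
#'
#' Bundles every tunable of the full pipeline: the simulation spec (or a
#' container path with epoched data), the TFR method, baseline variants,
#' spectral-parameterization settings, pACF settings, statistics options,
#' the ERP-subtraction flag, output directory and master seed. Validation
#' happens before any compute.
#'
#' @param simulation a [GroundTruthSpec-class], or NULL when `inputPath`
#'   is given.
#' @param inputPath container file holding an [EpochedData-class].
#' @param tfr list of [tfrEpochs()] arguments.
#' @param baselines list of `list(method =, window =)` baseline specs.
#' @param specparam [specParamSettings()] list. @param specWindow analysis
#'   window (s). @param timeStride see [parameterizeTFR()].
#' @param pacf NULL to skip, or list of [pacfEpochs()] arguments.
#' @param stats list with `q`, `minTime`, `minChannels`.
#' @param subtractErp logical.
#' @param outDir output directory. @param seed master seed.
#' @return validated config (class `specsift_config`).
#' @export
analysisConfig <- function(simulation = NULL, inputPath = NULL,
                           tfr = list(), baselines = list(
                             list(method = "decibel", window = c(-0.5, -0.2))),
                           specparam = specParamSettings(),
                           specWindow = c(-0.5, 2), timeStride = 1L,
                           pacf = NULL,
                           stats = list(q = 0.05, minTime = 3L,
                                        minChannels = 3L),
                           subtractErp = TRUE,
                           outDir = tempfile("specsift_run"), seed = 1L) {
  if (is.null(simulation) && is.null(inputPath)) {
    stop("either a simulation spec or an input path is required",
         call. = FALSE)
  }
  if (!is.null(inputPath) && !file.exists(inputPath)) {
    stop("input path does not exist: ", inputPath, call. = FALSE)
  }
  if (!is.null(simulation)) validObject(simulation)
  for (b in baselines) {
    if (!(b$window[1] < b$window[2] && b$window[2] <= 0)) {
      stop("invalid baseline window", call. = FALSE)
    }
    if (!is.null(simulation) &&
        b$window[1] < simulation@epochWindow[1]) {
      stop("baseline window outside the epoch", call. = FALSE)
    }
  }
  structure(list(simulation = simulation, inputPath = inputPath, tfr = tfr,
                 baselines = baselines, specparam = specparam,
                 specWindow = specWindow, timeStride = timeStride,
                 pacf = pacf, stats = stats, subtractErp = subtractErp,
                 outDir = outDir, seed = as.integer(seed)),
            class = "specsift_config")
}

#' Read an analysis configuration from YAML
#'
#' Thin front end for [analysisConfig()]: reads a YAML file whose keys
#' mirror the function arguments (`simulation` entries become a
#' [groundTruthSpec()] call).
#'
#' @param path YAML file.
#' @return a validated config.
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(groundTruthSpec, y$simulation)
  }
  for (nm in c("specWindow")) if (!is.null(y[[nm]])) y[[nm]] <- as.numeric(y[[nm]])
  if (!is.null(y$baselines)) {
    y$baselines <- lapply(y$baselines, function(b) {
      b$window <- as.numeric(b$window); b
    })
  }
  do.call(analysisConfig, y)
}

logStage <- function(log, stage, t0) {
  elapsed <- as.numeric(Sys.time()) - t0
  message(sprintf("[%s] done in %.1f s", stage, elapsed))
  c(log, setNames(list(elapsed), stage))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> ERP computation/subtraction -> TFR ->
#' baseline variants -> per-timepoint spectral parameterization -> pACF ->
#' condition statistics, persisting the results bundle into the output
#' directory. All stochastic stages consume the master seed, so identical
#' config + seed reproduces the bundle exactly.
#'
#' @param config from [analysisConfig()].
#' @return results bundle (named list; class `specsift_bundle`) with
#'   elements `epochs`, `erp`, `tfr`, `baselined`, `params`, `pacf`,
#'   `stats`, `rtSummaries`, and a run `manifest`.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "specsift_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$simulation)) {
    spec <- config$simulation
    spec@seed <- as.integer(deriveSeed(config$seed, spec@seed))
    epochs <- simulateEpochs(spec)
  } else {
    epochs <- readContainer(config$inputPath)
  }
  timings <- logStage(timings, "epochs", t0)

  t0 <- as.numeric(Sys.time())
  erp <- computeERP(epochs)
  analysed <- if (config$subtractErp) subtractERP(epochs, erp) else epochs
  timings <- logStage(timings, "erp", t0)

  t0 <- as.numeric(Sys.time())
  tfr <- do.call(tfrEpochs, c(list(analysed), config$tfr))
  timings <- logStage(timings, "tfr", t0)

  t0 <- as.numeric(Sys.time())
  baselined <- lapply(config$baselines, function(b) {
    applyBaseline(tfr, b$method, b$window)
  })
  names(baselined) <- vapply(config$baselines, function(b) {
    sprintf("%s_%g_%g", b$method, b$window[1], b$window[2])
  }, character(1))
  timings <- logStage(timings, "baseline", t0)

  t0 <- as.numeric(Sys.time())
  params <- parameterizeTFR(tfr, config$specparam, config$specWindow,
                            config$timeStride)
  timings <- logStage(timings, "specparam", t0)

  pac <- NULL
  if (!is.null(config$pacf)) {
    t0 <- as.numeric(Sys.time())
    pac <- do.call(pacfEpochs, c(list(analysed), config$pacf))
    timings <- logStage(timings, "pacf", t0)
  }

  t0 <- as.numeric(Sys.time())
  rtSummaries <- rtSummaryTable(epochs)
  stats <- NULL
  if (nrow(unique(epochs@conditionTable)) > 1L) {
    rtCell <- matrix(rtSummaries$mu, nrow = dim(epochs@samples)[1])
    stats <- massUnivariateConditions(
      params@exponent, epochs@conditionTable, rtPerCell = rtCell,
      q = config$stats$q, minTime = config$stats$minTime,
      minChannels = config$stats$minChannels,
      channelNames = epochs@channelNames, times = params@times)
  }
  timings <- logStage(timings, "stats", t0)

  bundle <- structure(list(
    epochs = epochs, erp = erp, tfr = tfr, baselined = baselined,
    params = params, pacf = pac, stats = stats, rtSummaries = rtSummaries,
    manifest = list(seed = config$seed, timings = timings,
                    configHash = digestConfig(config))
  ), class = "specsift_bundle")
  writeContainer(bundle, file.path(config$outDir, "results.sift"))
  bundle
}

# Stable hash of the config (numbers rounded to avoid printf jitter).
digestConfig <- function(config) {
  txt <- paste(utils::capture.output(str(config, digits.d = 10)),
               collapse = "\n")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 997 + 1)) %% 2147483647
}

# Per-cell reaction-time summaries (ex-Gaussian mu, sigma, tau).
rtSummaryTable <- function(epochs) {
  d <- dim(epochs@reactionTimes)
  out <- expand.grid(subject = seq_len(d[1]), condition = seq_len(d[2]))
  pars <- t(apply(out, 1, function(row) {
    exGaussMu(epochs@reactionTimes[row[1], row[2], ])
  }))
  cbind(out, mu = pars[, 1], sigma = pars[, 2], tau = pars[, 3])
}

#' Render report figures from a results bundle
#'
#' Writes the key diagnostic figures: the four-panel raw /
#' baseline-corrected / periodic / aperiodic view, the exponent
#' timecourses with condition overlays, and (when present) the mean pACF
#' spectrum. Figures missing their inputs are skipped with a message.
#'
#' @param bundle from [runFullAnalysis()].
#' @param outdir output directory for PNG files.
#' @return character vector of files written, invisibly.
#' @export
report <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tfr <- bundle$tfr
  params <- bundle$params

  gmean <- function(arr, dims) apply(arr, dims, mean, na.rm = TRUE)

  panelDf <- function(mat, freqs, times, panel) {
    data.frame(freq = rep(freqs, times = length(times)),
               time = rep(times, each = length(freqs)),
               value = as.vector(mat), panel = panel)
  }

  f1 <- file.path(outdir, "decomposition.png")
  ok <- tryCatch({
    raw <- gmean(tfr@power, c(4, 5))
    db <- gmean(bundle$baselined[[1]], c(4, 5))
    sel <- nearestIndex(tfr@times, params@times)
    per <- gmean(params@periodic, c(4, 5))
    expo <- gmean(params@exponent, 4)
    dfs <- rbind(
      panelDf(log10(raw[, sel]), tfr@frequencies, params@times,
              "raw log10 power"),
      panelDf(db[, sel], tfr@frequencies, params@times,
              "baseline-corrected (dB)"),
      panelDf(per, params@frequencies, params@times, "periodic (log10)")
    )
    g1 <- ggplot2::ggplot(dfs, ggplot2::aes(time, freq,
                                            fill = value)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~panel, scales = "free") +
      ggplot2::scale_fill_viridis_c(name = NULL) +
      ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
    g2 <- ggplot2::ggplot(data.frame(time = params@times, exponent = expo),
                          ggplot2::aes(time, exponent)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "aperiodic exponent",
                    title = "aperiodic component")
    grDevices::png(f1, width = 1400, height = 900, res = 140)
    print(g1)
    grDevices::dev.off()
    f2 <- file.path(outdir, "exponent_timecourse.png")
    grDevices::png(f2, width = 900, height = 600, res = 140)
    print(g2)
    grDevices::dev.off()
    written <- c(written, f1, f2)
    TRUE
  }, error = function(e) {
    message("decomposition figure skipped: ", conditionMessage(e))
    FALSE
  })

  if (!is.null(bundle$pacf)) {
    f3 <- file.path(outdir, "pacf.png")
    tryCatch({
      pac <- apply(bundle$pacf@pacf, c(4, 5), mean, na.rm = TRUE)
      df <- panelDf(pac, bundle$pacf@frequencies, bundle$pacf@times, "pACF")
      g3 <- ggplot2::ggplot(df, ggplot2::aes(time, freq,
                                             fill = value)) +
        ggplot2::geom_raster() +
        ggplot2::scale_fill_viridis_c(name = "pACF") +
        ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
      grDevices::png(f3, width = 900, height = 600, res = 140)
      print(g3)
      grDevices::dev.off()
      written <- c(written, f3)
    }, error = function(e) {
      message("pACF figure skipped: ", conditionMessage(e))
    })
  } else {
    message("pACF figure skipped: no rhythmicity map in the bundle")
  }

  if (!is.null(bundle$stats)) {
    f4 <- file.path(outdir, "condition_effects.png")
    tryCatch({
      dfs <- do.call(rbind, lapply(names(bundle$stats), function(tm) {
        sm <- bundle$stats[[tm]]
        data.frame(term = tm, time = sm@times,
                   nsig = apply(sm@clusterMask, 3, sum))
      }))
      g4 <- ggplot2::ggplot(dfs, ggplot2::aes(time, nsig)) +
        ggplot2::geom_line() + ggplot2::facet_wrap(~term) +
        ggplot2::labs(x = "time (s)",
                      y = "# channels significant (cluster-filtered)")
      grDevices::png(f4, width = 1200, height = 800, res = 140)
      print(g4)
      grDevices::dev.off()
      written <- c(written, f4)
    }, error = function(e) {
      message("condition-effects figure skipped: ", conditionMessage(e))
    })
  }
  invisible(written)
}
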