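#' Construct a ground-truth simulation specification
#'
#' Builds a [GroundTruthSpec-class] with defaults emulating a continuous
#' working-memory EEG study: 20 subjects, a 2 (modality) x 2 (load) x 2
#' (stimulus type) condition design collapsed to the cells requested, 30
#' trials per cell, 4 channels with frontal/parietal/occipital group
#' weights, 200 Hz sampling, epochs from -1.5 to 2.8 s around the stimulus.
#' The default dynamics plant two Gaussian-in-time aperiodic-exponent
#' events (frontal at 0.3 s, parietal at 0.7 s), a 10 Hz alpha and a 20 Hz
#' beta oscillation with post-stimulus suppression, a phase-locked ERP
#' transient, and ex-Gaussian reaction times.
#'
#' @param nSubjects,trialsPerCondition,samplingRate,epochWindow see slots.
#' @param conditionTable data.frame with columns `modality`, `load`,
#'   `stimulus`; defaults to the full 2 x 2 x 2 crossing.
#' @param channelNames,channelGroups channel labels and named per-channel
#'   weight lists in `[0, 1]`.
#' @param aperiodicOffset,aperiodicExponent baseline b0 and chi0.
#' @param exponentEvents,oscillations,erpTemplate component lists; see
#'   [GroundTruthSpec-class]. Pass `list()`/`NULL` to disable.
#' @param subjectRandomSD,sensorNoiseSD,rtModel,seed see slots.
#' @return a validated [GroundTruthSpec-class] object.
#' @export
groundTruthSpec <- function(nSubjects = 20,
                            trialsPerCondition = 30,
                            conditionTable = NULL,
                            channelNames = c("Fz", "Cz", "Pz", "Oz"),
                            channelGroups = NULL,
                            samplingRate = 200,
                            epochWindow = c(-1.5, 2.8),
                            aperiodicOffset = 0,
                            aperiodicExponent = 1,
                            exponentEvents = NULL,
                            oscillations = NULL,
                            erpTemplate = NULL,
                            subjectRandomSD = 0.1,
                            sensorNoiseSD = 0.1,
                            rtModel = NULL,
                            seed = 1L) {
  if (is.null(conditionTable)) {
    conditionTable <- expand.grid(
      modality = c("visuospatial", "verbal"),
      load = c("0back", "2back"),
      stimulus = c("nontarget", "target"),
      stringsAsFactors = FALSE
    )
  }
  nCh <- length(channelNames)
  if (is.null(channelGroups)) {
    channelGroups <- list(
      frontal = c(1, 0.5, 0, 0)[seq_len(nCh)],
      parietal = c(0, 0.5, 1, 0.5)[seq_len(nCh)],
      occipital = c(0, 0, 0.5, 1)[seq_len(nCh)],
      all = rep(1, nCh)
    )
    channelGroups <- lapply(channelGroups, function(g) {
      g[is.na(g)] <- 0; g
    })
  }
  if (is.null(exponentEvents)) {
    exponentEvents <- list(
      list(latency = 0.3, width = 0.15, amplitude = 0.3, group = "frontal"),
      list(latency = 0.7, width = 0.2, amplitude = 0.25, group = "parietal")
    )
  }
  if (is.null(oscillations)) {
    oscillations <- list(
      list(freq = 10, amplitude = 0.3, preLevel = 1, suppressionOnset = 0.2,
           suppressionDuration = 0.5, suppressionDepth = 0.5,
           group = "occipital"),
      list(freq = 20, amplitude = 0.15, preLevel = 1, suppressionOnset = 0.2,
           suppressionDuration = 0.5, suppressionDepth = 0.4,
           group = "parietal")
    )
  }
  if (missing(erpTemplate)) {
    erpTemplate <- list(amplitude = 0.4, latency = 0.25, width = 0.06,
                        group = "frontal")
  }
  if (is.null(rtModel)) {
    rtModel <- data.frame(mu = 0.5, sigma = 0.05, tau = 0.15)
  }
  if (nrow(rtModel) == 1L) {
    rtModel <- rtModel[rep(1L, nrow(conditionTable)), , drop = FALSE]
  }
  rownames(rtModel) <- NULL
  new("GroundTruthSpec",
      nSubjects = as.integer(nSubjects),
      trialsPerCondition = as.integer(trialsPerCondition),
      conditionTable = conditionTable,
      channelNames = channelNames,
      channelGroups = channelGroups,
      samplingRate = samplingRate,
      epochWindow = epochWindow,
      aperiodicOffset = aperiodicOffset,
      aperiodicExponent = aperiodicExponent,
      exponentEvents = exponentEvents,
      oscillations = oscillations,
      erpTemplate = erpTemplate,
      subjectRandomSD = subjectRandomSD,
      sensorNoiseSD = sensorNoiseSD,
      rtModel = rtModel,
      seed = as.integer(seed))
}

#' Simulate ex-Gaussian reaction times
#'
#' Independent draws of `Normal(mu, sigma^2) + Exponential(mean tau)`, the
#' standard positively skewed reaction-time model.
#'
#' @param mu,sigma,tau ex-Gaussian parameters in seconds (all > 0).
#' @param n number of draws (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return numeric vector of reaction times in seconds.
#' @examples
#' mean(simulateRTs(0.5, 0.05, 0.15, 1e4, seed = 7))  # ~ mu + tau = 0.65
#' @export
simulateRTs <- function(mu, sigma, tau, n, seed = 1L) {
  if (mu <= 0 || sigma <= 0 || tau <= 0) {
    stop("mu, sigma and tau must all be > 0", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  withSeed(seed, rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau))
}

# Oscillation amplitude envelope: flat pre-stimulus level, raised-cosine
# ramp down to (1 - depth) across the suppression interval, then sustained.
suppressionEnvelope <- function(times, onset, duration, depth) {
  env <- rep(1, length(times))
  if (depth <= 0 || duration <= 0) return(env)
  ramp <- times >= onset & times < onset + duration
  after <- times >= onset + duration
  ph <- (times[ramp] - onset) / duration
  env[ramp] <- 1 - depth * (0.5 - 0.5 * cos(pi * ph))
  env[after] <- 1 - depth
  env
}

conditionModifier <- function(component, condLabel) {
  cm <- component$conditionMod
  if (is.null(cm)) return(1)
  if (!condLabel %in% names(cm)) return(1)
  unname(cm[[condLabel]])
}

#' Simulate epoched EEG with known periodic and aperiodic dynamics
#'
#' Generates single-trial epoched EEG as the sum of (i) an aperiodic 1/f
#' track whose exponent timecourse is the subject baseline plus
#' Gaussian-in-time event bumps weighted by channel group and condition,
#' (ii) oscillations with per-trial uniform-random phase and a
#' post-stimulus suppression envelope, (iii) a phase-locked ERP template
#' identical across trials, and (iv) white sensor noise. Subject-level
#' offsets/exponents are drawn once per subject; reaction times come from
#' the condition's ex-Gaussian model. Fully reproducible given the spec's
#' master seed, which deterministically spawns per-subject/trial/channel
#' substreams.
#'
#' @param spec a [GroundTruthSpec-class].
#' @return an [EpochedData-class] object.
#' @export
simulateEpochs <- function(spec) {
  validObject(spec)
  fs <- spec@samplingRate
  nT <- round((spec@epochWindow[2] - spec@epochWindow[1]) * fs) + 1L
  times <- spec@epochWindow[1] + (seq_len(nT) - 1L) / fs
  nS <- spec@nSubjects
  nC <- nrow(spec@conditionTable)
  nR <- spec@trialsPerCondition
  nCh <- length(spec@channelNames)
  condLabels <- do.call(paste, c(spec@conditionTable, sep = "."))

  samples <- array(0, dim = c(nS, nC, nR, nCh, nT))
  rts <- array(NA_real_, dim = c(nS, nC, nR))
  acc <- array(TRUE, dim = c(nS, nC, nR))

  groupW <- function(name) spec@channelGroups[[name]]

  # ERP template per channel (identical across trials -> phase-locked)
  erp <- matrix(0, nCh, nT)
  if (!is.null(spec@erpTemplate)) {
    e <- spec@erpTemplate
    bump <- e$amplitude * exp(-(times - e$latency)^2 / (2 * e$width^2))
    erp <- outer(groupW(e$group), bump)
  }

  sdB <- spec@subjectRandomSD[1]
  sdChi <- spec@subjectRandomSD[length(spec@subjectRandomSD)]

  for (s in seq_len(nS)) {
    subjPar <- withSeed(deriveSeed(spec@seed, 1L, s), rnorm(2))
    b0 <- spec@aperiodicOffset + sdB * subjPar[1]
    chi0 <- max(0, spec@aperiodicExponent + sdChi * subjPar[2])
    for (cc in seq_len(nC)) {
      # channel-wise exponent and offset timecourses (shared across trials);
      # each event rotates the spectrum about its pivot frequency, so the
      # offset co-varies as delta-b = delta-chi * log10(pivotHz)
      chiT <- matrix(chi0, nCh, nT)
      bT <- matrix(b0, nCh, nT)
      for (ev in spec@exponentEvents) {
        bump <- ev$amplitude * conditionModifier(ev, condLabels[cc]) *
          exp(-(times - ev$latency)^2 / (2 * ev$width^2))
        chBump <- outer(groupW(ev$group), bump)
        chiT <- chiT + chBump
        pivot <- if (is.null(ev$pivotHz)) 20 else ev$pivotHz
        if (pivot > 0) bT <- bT + chBump * log10(pivot)
      }
      chiT[chiT < 0] <- 0
      # oscillation envelopes per channel (shared across trials)
      oscEnv <- lapply(spec@oscillations, function(osc) {
        depth <- min(1, max(0, osc$suppressionDepth *
                              conditionModifier(osc, condLabels[cc])))
        amp <- osc$amplitude * (if (is.null(osc$preLevel)) 1 else osc$preLevel)
        outer(amp * groupW(osc$group),
              suppressionEnvelope(times, osc$suppressionOnset,
                                  osc$suppressionDuration, depth))
      })
      for (r in seq_len(nR)) {
        ph <- withSeed(deriveSeed(spec@seed, 2L, s, cc, r),
                       runif(max(1L, length(spec@oscillations)), 0, 2 * pi))
        noise <- withSeed(deriveSeed(spec@seed, 4L, s, cc, r),
                          matrix(rnorm(nCh * nT, 0, spec@sensorNoiseSD),
                                 nCh, nT))
        for (ch in seq_len(nCh)) {
          x <- simulateAperiodicTimeseries(
            chiT[ch, ], bT[ch, ], fs, duration = nT / fs,
            seed = deriveSeed(spec@seed, 3L, s, cc, r, ch)
          )[seq_len(nT)]
          for (k in seq_along(spec@oscillations)) {
            f0 <- spec@oscillations[[k]]$freq
            x <- x + oscEnv[[k]][ch, ] * sin(2 * pi * f0 * times + ph[k])
          }
          samples[s, cc, r, ch, ] <- x + erp[ch, ] + noise[ch, ]
        }
      }
      rtp <- spec@rtModel[cc, ]
      rts[s, cc, ] <- simulateRTs(rtp$mu, rtp$sigma, rtp$tau, nR,
                                  seed = deriveSeed(spec@seed, 5L, s, cc))
    }
  }

  new("EpochedData",
      samples = samples,
      samplingRate = fs,
      times = times,
      channelNames = spec@channelNames,
      conditionTable = spec@conditionTable,
      reactionTimes = rts,
      accuracy = acc,
      subjectIds = sprintf("S%02d", seq_len(nS)))
}
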