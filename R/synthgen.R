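# Synthetic multichannel iEEG with the statistical structure the analyses
# assume: 1/f background plus a shared common-mode component, plantable
# narrowband theta "safety" power during extinction CS- trials, item- and
# context-specific spectral-spatial signatures, epileptiform-like transients,
# and behavioural ratings following a learning curve.

#' Synthetic-recording generator configuration
#'
#' Parameters of the iEEG generator. Defaults reproduce the study
#' conditions: 1 kHz sampling, ROI channel counts near the reported
#' per-participant means, 1/f background, and planted effects mirroring the
#' reported phenomena (higher theta power for currently safe cues late in
#' the extinction cue period; more stable CS++ item patterns during
#' extinction; context-specific patterns strongest during extinction).
#' Effect amplitudes are in microvolts (SD of the added band-limited
#' component) and default to values giving in-band SNR near 1 against the
#' background spectral density.
#'
#' @param samplingRate Hz (default 1000; must exceed twice the highest
#'   analysis frequency, 100 Hz).
#' @param rois named integer vector: channels per ROI.
#' @param noiseExponent exponent of the 1/f^a background power spectrum.
#' @param noiseAmplitude per-channel background SD in microvolts.
#' @param commonGain amplitude of the shared (common-mode) component,
#'   relative to \code{noiseAmplitude}; removed by bipolar referencing.
#' @param thetaSafetyEffect SD (microvolts) of the flat 3-10 Hz component
#'   added to \code{thetaRois} channels in extinction trials whose current
#'   valence is CS-, within \code{thetaWindow} after cue onset.
#' @param thetaBand,thetaWindow band (Hz) and window (s post-cue) of the
#'   planted theta effect.
#' @param thetaRois ROIs receiving the theta effect.
#' @param itemPatternGain base SD (microvolts) of the per-cue
#'   channel x frequency signature expressed during cue presentation.
#' @param itemGainProfile 3 x 3 matrix (roles x phases) of multipliers on
#'   \code{itemPatternGain}; the default makes CS++ patterns the most
#'   stable during extinction with no condition differences elsewhere.
#' @param contextPatternGain base SD (microvolts) of the per-context
#'   signature expressed during video + cue presentation.
#' @param contextGainProfile named per-phase multipliers on
#'   \code{contextPatternGain} (strongest during extinction).
#' @param patternJitter trial-to-trial SD of signature expression
#'   (multiplicative, 1 + N(0, jitter), truncated at 0).
#' @param artifactRate epileptiform-like transients per minute per channel.
#' @param artifactAmplitudeSD transient amplitude in multiples of the
#'   channel SD.
#' @param seed RNG seed.
#' @return list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(samplingRate = 1000,
                            rois = c(TMP = 7, AMY = 3, HPC = 3, OFC = 3,
                                     lPFC = 3),
                            noiseExponent = 1, noiseAmplitude = 30,
                            commonGain = 0.5,
                            thetaSafetyEffect = 12,
                            thetaBand = c(3, 10),
                            thetaWindow = c(1.18, 1.75),
                            thetaRois = "AMY",
                            itemPatternGain = 12,
                            itemGainProfile = NULL,
                            contextPatternGain = 12,
                            contextGainProfile = c(acquisition = 0.5,
                                                   extinction = 1,
                                                   test = 0.5),
                            patternJitter = 0.2,
                            artifactRate = 0.02,
                            artifactAmplitudeSD = 15,
                            seed = 1) {
  if (samplingRate <= 200)
    stop("samplingRate must exceed twice the highest analysis frequency")
  if (any(c(thetaSafetyEffect, itemPatternGain, contextPatternGain) < 0))
    stop("effect gains must be >= 0")
  if (is.null(itemGainProfile)) {
    itemGainProfile <- rbind("CS++" = c(0.7, 1.0, 0.7),
                             "CS+-" = c(0.7, 0.4, 0.7),
                             "CS--" = c(0.7, 0.4, 0.7))
    colnames(itemGainProfile) <- c("acquisition", "extinction", "test")
  }
  cfg <- list(samplingRate = samplingRate, rois = rois,
              noiseExponent = noiseExponent,
              noiseAmplitude = noiseAmplitude, commonGain = commonGain,
              thetaSafetyEffect = thetaSafetyEffect, thetaBand = thetaBand,
              thetaWindow = thetaWindow, thetaRois = thetaRois,
              itemPatternGain = itemPatternGain,
              itemGainProfile = itemGainProfile,
              contextPatternGain = contextPatternGain,
              contextGainProfile = contextGainProfile,
              patternJitter = patternJitter, artifactRate = artifactRate,
              artifactAmplitudeSD = artifactAmplitudeSD, seed = seed)
  class(cfg) <- "GeneratorConfig"
  cfg
}

# Cache of 1/f^a spectral envelopes keyed by length/rate/exponent.
.ampCache <- new.env(parent = emptyenv())

# Colored (1/f^a) Gaussian noise of length n, unit SD.
.coloredNoise <- function(n, exponent, samplingRate) {
  nfft <- .goodFFTLength(n)
  nhalf <- floor(nfft / 2)
  key <- paste(nfft, samplingRate, exponent, sep = "|")
  amp <- .ampCache[[key]]
  if (is.null(amp)) {
    f <- seq_len(nhalf) * samplingRate / nfft
    amp <- f^(-exponent / 2)
    .ampCache[[key]] <- amp
  }
  spec <- complex(real = stats::rnorm(nhalf), imaginary = stats::rnorm(nhalf)) * amp
  full <- complex(length.out = nfft)
  full[2:(nhalf + 1)] <- spec
  full[nfft:(nfft - nhalf + 2)] <- Conj(spec[seq_len(nhalf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# Band-limited Gaussian noise of length n whose amplitude spectrum follows
# `profile(f)` (a function of Hz) or a precomputed per-bin amplitude vector
# `amp`, scaled to unit SD, Tukey-tapered.
.shapedNoise <- function(n, profile = NULL, samplingRate = NULL,
                         taper = 0.2, amp = NULL) {
  nfft <- .goodFFTLength(max(n, 64))
  nhalf <- floor(nfft / 2)
  if (is.null(amp)) {
    f <- seq_len(nhalf) * samplingRate / nfft
    amp <- profile(f)
  }
  if (all(amp == 0)) return(numeric(n))
  spec <- complex(real = stats::rnorm(nhalf), imaginary = stats::rnorm(nhalf)) * amp
  full <- complex(length.out = nfft)
  full[2:(nhalf + 1)] <- spec
  full[nfft:(nfft - nhalf + 2)] <- Conj(spec[seq_len(nhalf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x <- x / s
  # Tukey taper to avoid onset/offset discontinuities
  m <- max(2L, round(taper * n / 2))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  x[seq_len(m)] <- x[seq_len(m)] * ramp
  x[(n - m + 1):n] <- x[(n - m + 1):n] * rev(ramp)
  x
}

# Linear interpolation of a 44-point frequency template onto arbitrary Hz.
.templateProfile <- function(template, gridFreqs) {
  function(f) {
    out <- stats::approx(gridFreqs, template, xout = f, rule = 1)$y
    out[is.na(out)] <- 0
    out
  }
}

.channelInfoFromRois <- function(rois) {
  do.call(rbind, lapply(names(rois), function(r) {
    n <- rois[[r]]
    data.frame(channel = sprintf("%s%d", r, seq_len(n)), shaft = r,
               contact = seq_len(n), roi = r)
  }))
}

#' Simulate a continuous multichannel iEEG recording
#'
#' Builds a continuous recording spanning all trials of the supplied
#' schedules (phases concatenated in order), with event markers at video,
#' cue and US onsets, 1/f background plus a shared common-mode component,
#' and the configured planted effects: a theta-band power increase for
#' currently safe cues during extinction, per-cue item signatures during cue
#' presentation, and per-context signatures during video + cue presentation.
#' Signature templates are fixed random nonnegative channel x frequency
#' arrays, unit-normalized before gain scaling. Deterministic per seed.
#'
#' @param schedules list of TrialSchedules (any subset of the phases, in
#'   presentation order), as from \code{\link{generateExperiment}}.
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{recording} (a \linkS4class{Recording}) and
#'   \code{groundTruth} (templates, planted windows/bands, artifact ledger,
#'   seed).
#' @export
simulateRecording <- function(schedules, config = generatorConfig()) {
  phases <- intersect(c("acquisition", "extinction", "test"),
                      names(schedules))
  if (!length(phases)) stop("schedules must contain at least one phase")
  fs <- config$samplingRate
  iti <- attr(schedules[[phases[1]]], "design")$timing[["iti"]]
  if (iti < 0) stop("inter-trial interval must be non-negative")
  set.seed(config$seed)

  chans <- .channelInfoFromRois(config$rois)
  nCh <- nrow(chans)
  grid <- buildFrequencyGrid()

  # trial timeline
  allTrials <- do.call(rbind, lapply(phases, function(p) {
    s <- as.data.frame(schedules[[p]])
    s
  }))
  trialLen <- allTrials$duration + iti
  if (any(allTrials$duration <= allTrials$onset_us))
    stop("trial timings overlap: US onset beyond trial duration")
  starts <- cumsum(c(0, trialLen[-nrow(allTrials)]))
  nSamples <- ceiling(sum(trialLen) * fs)
  startSmp <- round(starts * fs) + 1L

  events <- do.call(rbind, lapply(seq_len(nrow(allTrials)), function(i) {
    tr <- allTrials[i, ]
    data.frame(
      sample = startSmp[i] + round(c(tr$onset_video, tr$onset_cue,
                                     tr$onset_us) * fs),
      marker = c("video", "cue", "us"),
      phase = tr$phase, trial = tr$index)
  }))

  # signature templates: fixed nonnegative channel x frequency arrays
  cues <- sort(unique(allTrials$cue_id))
  mkTemplate <- function() {
    t <- abs(matrix(stats::rnorm(nCh * length(grid$freqs)), nCh))
    t / sqrt(sum(t^2))
  }
  cueTemplates <- lapply(cues, function(i) mkTemplate())
  names(cueTemplates) <- as.character(cues)
  ctxIds <- sort(unique(allTrials$context_id))
  ctxTemplates <- lapply(ctxIds, function(i) mkTemplate())
  names(ctxTemplates) <- as.character(ctxIds)

  # background: independent 1/f per channel + one shared component
  data <- matrix(0, nCh, nSamples)
  common <- .coloredNoise(nSamples, config$noiseExponent, fs)
  for (ch in seq_len(nCh)) {
    data[ch, ] <- config$noiseAmplitude *
      (.coloredNoise(nSamples, config$noiseExponent, fs) +
         config$commonGain * common)
  }

  thetaCh <- which(chans$roi %in% config$thetaRois)
  bandLo <- config$thetaBand[1]; bandHi <- config$thetaBand[2]
  thetaProfile <- function(f) as.numeric(f >= bandLo & f <= bandHi)

  jit <- function() max(0, 1 + stats::rnorm(1, 0, config$patternJitter))

  # precompute per-template/channel spectral amplitude vectors for the two
  # expression-window lengths (cue and video+cue)
  binFreqs <- function(len) {
    nfft <- .goodFFTLength(max(len, 64))
    seq_len(floor(nfft / 2)) * fs / nfft
  }
  tr1 <- allTrials[1, ]
  cueLen <- round((tr1$onset_us - tr1$onset_cue) * fs)
  vidLen <- round((tr1$onset_us - tr1$onset_video) * fs)
  fCue <- binFreqs(cueLen); fVid <- binFreqs(vidLen)
  precompute <- function(templates, f) {
    lapply(templates, function(tpl) {
      lapply(seq_len(nCh), function(ch) {
        .templateProfile(tpl[ch, ], grid$freqs)(f)
      })
    })
  }
  cueAmp <- precompute(cueTemplates, fCue)
  ctxAmp <- precompute(ctxTemplates, fVid)
  thetaAmpSpec <- thetaProfile(binFreqs(round(diff(config$thetaWindow) *
                                                fs)))

  for (i in seq_len(nrow(allTrials))) {
    tr <- allTrials[i, ]
    s0 <- startSmp[i]

    # item signature during cue presentation
    gItem <- config$itemPatternGain *
      config$itemGainProfile[tr$role, tr$phase]
    if (gItem > 0) {
      tplId <- as.character(tr$cue_id)
      tpl <- cueTemplates[[tplId]]
      idx <- s0 + round(tr$onset_cue * fs) + seq_len(cueLen) - 1L
      g <- gItem * jit()
      for (ch in seq_len(nCh)) {
        sCh <- sqrt(sum(tpl[ch, ]^2))
        if (sCh == 0) next
        data[ch, idx] <- data[ch, idx] +
          g * sCh * .shapedNoise(cueLen, amp = cueAmp[[tplId]][[ch]])
      }
    }

    # context signature during video + cue
    gCtx <- config$contextPatternGain *
      config$contextGainProfile[[tr$phase]]
    if (gCtx > 0) {
      tplId <- as.character(tr$context_id)
      tpl <- ctxTemplates[[tplId]]
      idx <- s0 + round(tr$onset_video * fs) + seq_len(vidLen) - 1L
      g <- gCtx * jit()
      for (ch in seq_len(nCh)) {
        sCh <- sqrt(sum(tpl[ch, ]^2))
        if (sCh == 0) next
        data[ch, idx] <- data[ch, idx] +
          g * sCh * .shapedNoise(vidLen, amp = ctxAmp[[tplId]][[ch]])
      }
    }

    # theta safety effect: extinction, current valence CS-, theta ROIs
    if (config$thetaSafetyEffect > 0 && tr$phase == "extinction" &&
        tr$valence == "CS-" && length(thetaCh)) {
      w0 <- s0 + round((tr$onset_cue + config$thetaWindow[1]) * fs)
      len <- round(diff(config$thetaWindow) * fs)
      idx <- w0 + seq_len(len) - 1L
      for (ch in thetaCh) {
        data[ch, idx] <- data[ch, idx] + config$thetaSafetyEffect *
          .shapedNoise(len, amp = thetaAmpSpec)
      }
    }
  }

  rec <- new("Recording", data = data, samplingRate = fs,
             channelInfo = chans, events = events,
             processing = character())
  gt <- list(cueTemplates = cueTemplates, contextTemplates = ctxTemplates,
             thetaBand = config$thetaBand, thetaWindow = config$thetaWindow,
             thetaRois = config$thetaRois, artifacts = NULL,
             seed = config$seed)

  if (config$artifactRate > 0) {
    inj <- injectArtifacts(rec, rate = config$artifactRate,
                           amplitudeSD = config$artifactAmplitudeSD,
                           seed = .childSeed(config$seed, 97))
    rec <- inj$recording
    gt$artifacts <- inj$ledger
  }
  list(recording = rec, groundTruth = gt)
}

#' Inject epileptiform-like transients into a recording
#'
#' Adds brief (5-50 ms) biphasic spikes at Poisson-distributed positions per
#' channel and returns the position ledger for detector-sensitivity tests.
#'
#' @param recording a \linkS4class{Recording}.
#' @param rate transients per minute per channel.
#' @param amplitudeSD spike amplitude in multiples of the channel SD.
#' @param seed RNG seed.
#' @return list with \code{recording} (spikes added) and \code{ledger}
#'   (data.frame: channel, sample, durationMs, amplitude).
#' @export
injectArtifacts <- function(recording, rate, amplitudeSD, seed = 1) {
  if (rate == 0)
    return(list(recording = recording,
                ledger = data.frame(channel = integer(), sample = integer(),
                                    durationMs = numeric(),
                                    amplitude = numeric())))
  set.seed(seed)
  fs <- recording@samplingRate
  n <- ncol(recording@data)
  minutes <- n / fs / 60
  data <- recording@data
  rows <- list()
  for (ch in seq_len(nrow(data))) {
    k <- stats::rpois(1, rate * minutes)
    if (k == 0) next
    sdCh <- stats::sd(data[ch, ])
    pos <- sort(sample.int(n - 60, k))
    for (p in pos) {
      durMs <- stats::runif(1, 5, 50)
      len <- max(5L, round(durMs / 1000 * fs))
      amp <- amplitudeSD * sdCh
      shape <- amp * sin(2 * pi * seq_len(len) / len)
      idx <- p + seq_len(len) - 1L
      data[ch, idx] <- data[ch, idx] + shape
      rows[[length(rows) + 1]] <-
        data.frame(channel = ch, sample = p, durationMs = durMs,
                   amplitude = amp)
    }
  }
  recording@data <- data
  ledger <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = integer(), sample = integer(),
               durationMs = numeric(), amplitude = numeric())
  list(recording = recording, ledger = ledger)
}

#' Simulate trial-wise contingency ratings
#'
#' Generates 1 (threatening) to 4 (safe) ratings following a learning curve:
#' CS++ cues trend threatening, CS-- safe, and CS+- switches from
#' threatening to safe during extinction with a saturating transition
#' beginning at \code{learningOnset} (within-condition ordinal position).
#' During the test phase CS++ remains rated somewhat more threatening
#' (incomplete extinction). A fraction of trials carries no response.
#'
#' @param schedules list of TrialSchedules (as from
#'   \code{\link{generateExperiment}}).
#' @param learningOnset ordinal position at which learning transitions
#'   begin (default 10).
#' @param asymptoteGap asymptotic rating gap between threat and safe cues
#'   (rating units, default 3: asymptotes 1 and 4).
#' @param noiseSD rating noise SD before rounding (default 0.5).
#' @param missRate fraction of trials without a response (default 0.08).
#' @param transitionTau time constant (ordinal positions) of the saturating
#'   transition; near 0 gives an instant switch at onset.
#' @param seed RNG seed.
#' @return data.frame: phase, index, cue_id, role, ordinal, rating (NA =
#'   missing).
#' @export
simulateRatings <- function(schedules, learningOnset = 10, asymptoteGap = 3,
                            noiseSD = 0.5, missRate = 0.08,
                            transitionTau = 3, seed = 1) {
  set.seed(seed)
  mid <- 2.5
  threat <- mid - asymptoteGap / 2
  safe <- mid + asymptoteGap / 2
  trans <- function(k) {
    g <- ifelse(k >= learningOnset,
                1 - exp(-(k - learningOnset + 1) /
                          max(transitionTau, 1e-9)), 0)
    g
  }
  phases <- intersect(c("acquisition", "extinction", "test"),
                      names(schedules))
  out <- do.call(rbind, lapply(phases, function(p) {
    s <- as.data.frame(schedules[[p]])
    s$ordinal <- stats::ave(seq_len(nrow(s)), s$role, FUN = seq_along)
    base <- numeric(nrow(s))
    for (i in seq_len(nrow(s))) {
      role <- s$role[i]; k <- s$ordinal[i]
      base[i] <- switch(p,
        acquisition = {
          tgt <- if (role == "CS--") safe else threat
          mid + (tgt - mid) * trans(k)
        },
        extinction = switch(role,
          "CS++" = threat,
          "CS--" = safe,
          "CS+-" = threat + (safe - threat) * trans(k)),
        test = switch(role, "CS++" = 2, "CS+-" = 3, "CS--" = 3.5))
    }
    r <- round(pmin(4, pmax(1, base + stats::rnorm(nrow(s), 0, noiseSD))))
    r[stats::runif(nrow(s)) < missRate] <- NA
    data.frame(phase = p, index = s$index, cue_id = s$cue_id, role = s$role,
               ordinal = s$ordinal, rating = r)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of participants
#'
#' Draws per-participant experiments (counterbalanced schedules), synthetic
#' recordings and ratings. Heavy per-participant objects are kept only if
#' \code{keepRecordings} is TRUE; otherwise a caller-supplied \code{process}
#' function is applied to each participant and only its value retained, so
#' cohorts can be processed with bounded memory.
#'
#' @param nParticipants cohort size.
#' @param design a \code{\link{designConfig}}.
#' @param config a \code{\link{generatorConfig}} (per-participant seeds are
#'   derived from \code{seed}).
#' @param seed master seed.
#' @param phases phases to simulate (default all three).
#' @param process optional function(participant) applied immediately; its
#'   return value replaces the raw participant data.
#' @param ratings logical: also simulate ratings (default TRUE).
#' @return list of participants; each either the raw list (schedules,
#'   recording, groundTruth, ratings, seed) or the value of \code{process}.
#' @export
simulateCohort <- function(nParticipants, design = designConfig(),
                           config = generatorConfig(), seed = 1,
                           phases = c("acquisition", "extinction", "test"),
                           process = NULL, ratings = TRUE) {
  lapply(seq_len(nParticipants), function(i) {
    pseed <- .childSeed(seed, i)
    sch <- generateExperiment(design, seed = pseed)
    sch <- sch[c(intersect(names(sch), phases), "counterbalance")]
    cfg <- config
    cfg$seed <- .childSeed(pseed, 1)
    sim <- simulateRecording(sch, cfg)
    part <- list(
      id = i,
      schedules = sch,
      recording = sim$recording,
      groundTruth = sim$groundTruth,
      ratings = if (ratings) {
        simulateRatings(sch, seed = .childSeed(pseed, 2))
      },
      seed = pseed)
    if (is.null(process)) part else process(part)
  })
}
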