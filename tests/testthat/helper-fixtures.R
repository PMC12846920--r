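# Shared fixtures built in code: small recordings, hand-made schedules and
# pattern series used across test files.

# A white-noise Recording with one shaft, optional event train.
makeNoiseRecording <- function(nCh = 2, seconds = 60, fs = 1000, sd = 1,
                               seed = 1, roi = "AMY", events = NULL) {
  set.seed(seed)
  data <- matrix(rnorm(nCh * seconds * fs, sd = sd), nCh)
  ci <- data.frame(channel = paste0(roi, seq_len(nCh)), shaft = roi,
                   contact = seq_len(nCh), roi = roi)
  if (is.null(events))
    events <- data.frame(sample = integer(), marker = character(),
                         phase = character(), trial = integer())
  new("Recording", data = data, samplingRate = fs, channelInfo = ci,
      events = events, processing = character())
}

# A hand-made n-trial schedule (single phase) with cue events every `gap` s.
makeToySchedule <- function(n = 12, phase = "extinction", gap = 8,
                            cues = rep(1:3, length.out = 12),
                            contexts = rep(1:4, length.out = 12)) {
  roles <- c("CS++", "CS+-", "CS--")
  role <- roles[cues]
  sched <- data.frame(
    phase = phase, index = seq_len(n), cue_id = cues[seq_len(n)],
    role = role[seq_len(n)],
    valence = extinctRSA:::.currentValence(role[seq_len(n)], phase),
    context_id = contexts[seq_len(n)], us = FALSE,
    onset_fixation = 0, onset_video = 0.5, onset_cue = 2.5,
    onset_us = 4.25, duration = 7.25)
  attr(sched, "design") <- designConfig()
  class(sched) <- c("TrialSchedule", "data.frame")
  sched
}

# Events for a toy schedule laid on a recording: cue onsets at
# (4 + gap * (i-1)) seconds.
makeToyEvents <- function(sched, fs = 1000, start = 4, gap = 8) {
  do.call(rbind, lapply(seq_len(nrow(sched)), function(i) {
    cue <- round((start + gap * (i - 1)) * fs)
    data.frame(sample = c(cue - 2000, cue, cue + 1750),
               marker = c("video", "cue", "us"),
               phase = sched$phase[1], trial = i)
  }))
}

# PatternSeries from an explicit trials x features x windows array.
makePatterns <- function(feat, centers = NULL, lock = "cue",
                         trialInfo = NULL) {
  if (is.null(centers))
    centers <- seq(0.25, by = 0.05, length.out = dim(feat)[3])
  if (is.null(trialInfo))
    trialInfo <- data.frame(index = seq_len(dim(feat)[1]))
  new("PatternSeries", features = feat, centers = centers, lock = lock,
      trialInfo = trialInfo)
}

# Random-pattern participant for metric-level RSA tests: label-independent
# features plus an optional per-cue pattern bump.
makeRsaParticipant <- function(seed, nTrials = 72, nFeat = 60, nWin = 10,
                               cueGain = 0, phase = "extinction") {
  set.seed(seed)
  sch <- generateExperiment(seed = seed)[[phase]]
  feat <- array(rnorm(nTrials * nFeat * nWin), c(nTrials, nFeat, nWin))
  if (cueGain > 0) {
    tpl <- lapply(1:3, function(i) rnorm(nFeat))
    for (t in seq_len(nTrials)) {
      g <- if (sch$valence[t] == "CS+") cueGain else 0
      if (g > 0)
        feat[t, , ] <- feat[t, , ] + g * tpl[[sch$cue_id[t]]]
    }
  }
  list(sim = pairwiseSpearman(makePatterns(feat)), sched = sch)
}
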