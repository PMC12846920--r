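# End-to-end orchestration: configuration, per-participant processing
# (filter -> bipolar -> artifact detection -> epoching -> TFR -> z-score),
# cohort-level analysis drivers, and the report bundle.

# Polynomial rolling hash of a serialized R object (provenance stamp).
.configHash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 131 + b + 1) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles the design, generator and analysis parameters of a full
#' simulated-cohort run. All randomness flows from \code{seed}; per-stage
#' seeds are derived from it and recorded in the report.
#'
#' @param nParticipants cohort size (default 8).
#' @param design a \code{\link{designConfig}}.
#' @param generator a \code{\link{generatorConfig}}.
#' @param phases phases to simulate and analyse.
#' @param analysisRois named list: \code{theta}, \code{item},
#'   \code{context} ROI names.
#' @param freqRangeTheta band for the theta contrast (default c(1, 12)).
#' @param tfrWindow,timeStep TFR output window (cue-locked) and step.
#' @param nPerm permutations for all cluster tests.
#' @param minTrials per-condition minimum trial count (8).
#' @param contextWindow,itemWindow analysis windows (s) for the
#'   participant-level reinstatement metrics (defaults: the lPFC context
#'   specificity window 0.8-1.15 s and the TMP item-stability window
#'   0.65-1 s).
#' @param reinstatement logical: run the cross-phase reinstatement block
#'   (requires all three phases).
#' @param seed master seed.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(nParticipants = 8, design = designConfig(),
                           generator = generatorConfig(),
                           phases = c("acquisition", "extinction", "test"),
                           analysisRois = list(theta = "AMY", item = "TMP",
                                               context = "lPFC"),
                           freqRangeTheta = c(1, 12),
                           tfrWindow = c(0, 1.75), timeStep = 0.02,
                           nPerm = 1000, minTrials = 8,
                           contextWindow = c(0.8, 1.15),
                           itemWindow = c(0.65, 1),
                           reinstatement = TRUE, seed = 1) {
  cfg <- list(nParticipants = nParticipants, design = design,
              generator = generator, phases = phases,
              analysisRois = analysisRois,
              freqRangeTheta = freqRangeTheta, tfrWindow = tfrWindow,
              timeStep = timeStep, nPerm = nPerm, minTrials = minTrials,
              contextWindow = contextWindow, itemWindow = itemWindow,
              reinstatement = reinstatement, seed = seed)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema check naming the offending field on failure.
#'
#' @param config a list as from \code{\link{pipelineConfig}}.
#' @return TRUE invisibly, or an error naming the missing/invalid field.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("nParticipants", "design", "generator", "phases",
            "analysisRois", "nPerm", "seed")
  for (f in need) {
    if (is.null(config[[f]])) stop("config field missing: ", f)
  }
  for (f in c("theta", "item", "context")) {
    roi <- config$analysisRois[[f]]
    if (is.null(roi)) stop("config field missing: analysisRois$", f)
    if (!all(roi %in% names(config$generator$rois)))
      stop("analysisRois$", f, " not present in generator ROI definition")
  }
  if (config$nParticipants < 2) stop("config field invalid: nParticipants")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields in the YAML file override the defaults of
#' \code{\link{pipelineConfig}}; \code{design} and \code{generator}
#' sub-maps override the corresponding constructor arguments.
#'
#' @param path YAML file path.
#' @return a validated \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(designConfig, y$design %||% list())
  gen <- do.call(generatorConfig, y$generator %||% list())
  y$design <- NULL; y$generator <- NULL
  args <- c(list(design = design, generator = gen), y)
  do.call(pipelineConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Process one participant from raw recording to z-scored TFR per ROI
#'
#' Applies the preprocessing chain (zero-phase filtering, bipolar
#' referencing, artifact detection, cue-locked epoching with ROI-level
#' rejection) and the Morlet decomposition, then z-scores power per
#' channel x frequency against all trials of all processed phases.
#'
#' @param participant list with \code{recording} and \code{schedules} (as
#'   from \code{\link{simulateCohort}}).
#' @param rois ROI names to epoch and decompose.
#' @param grid frequency grid (default \code{\link{buildFrequencyGrid}}).
#' @param freqRange optional band restriction (Hz).
#' @param tfrWindow,timeStep TFR output window and step (s).
#' @param epochWindow epoch window (default c(-3, 4)).
#' @param edge edge handling for \code{\link{morletTFR}}.
#' @param minTrials per-condition minimum trial count.
#' @return list per ROI: list per phase with \code{tfr} (z-scored
#'   \linkS4class{TFRArray}) and \code{schedule} (retained-trial rows);
#'   plus \code{ratings} and \code{schedules} passed through.
#' @export
processParticipant <- function(participant, rois,
                               grid = buildFrequencyGrid(),
                               freqRange = NULL,
                               tfrWindow = c(0, 1.75), timeStep = 0.02,
                               epochWindow = c(-3, 4),
                               edge = "strict", minTrials = 8) {
  # Bipolar referencing first (a cheap subtraction), then one fused FFT
  # pass per virtual channel yields both the band/notch-filtered signal and
  # the 250 Hz high-passed signal; artifacts are detected on the raw
  # bipolar data (amplitude/gradient criteria) plus the high-passed signal.
  raw <- participant$recording
  fs <- raw@samplingRate
  if (fs <= 400) stop("sampling rate must exceed 400 Hz")
  bipRaw <- bipolarReference(raw)
  n <- ncol(bipRaw@data)
  h2band <- .evalH2(n, fs, function(f) {
    .butterHighpassH2(f, 0.1, 4) * .butterLowpassH2(f, 200, 4) *
      .butterBandstopH2(f, 49, 51, 4) * .butterBandstopH2(f, 99, 101, 4) *
      .butterBandstopH2(f, 149, 151, 4)
  }, key = "bandnotch-default")
  h2hf <- .evalH2(n, fs, function(f) .butterHighpassH2(f, 250, 4),
                  key = "hf 250")
  pair <- .fftFilterPair(bipRaw@data, fs, h2band, h2hf)
  mask <- detectArtifacts(bipRaw, hf = pair$hf)
  bip <- bipRaw
  bip@data <- pair$filtered
  bip@processing <- c(bip@processing, "filter")
  phases <- intersect(c("acquisition", "extinction", "test"),
                      names(participant$schedules))
  out <- list()
  for (roi in rois) {
    perPhase <- list()
    for (ph in phases) {
      ep <- epochRecording(bip, participant$schedules[[ph]], mask,
                           window = epochWindow, roi = roi,
                           minTrials = minTrials)
      tfr <- morletTFR(ep, grid, window = tfrWindow, timeStep = timeStep,
                       freqRange = freqRange, edge = edge)
      perPhase[[ph]] <- list(tfr = tfr, schedule = ep@trialInfo)
    }
    refs <- lapply(perPhase, function(x) x$tfr)
    for (ph in phases) {
      perPhase[[ph]]$tfr <- zscorePower(perPhase[[ph]]$tfr,
                                        reference = refs)
    }
    out[[roi]] <- perPhase
  }
  out$ratings <- participant$ratings
  out$schedules <- participant$schedules
  out
}

# Extract per-participant lists (tfr, labels, schedule) for one ROI/phase.
.cohortSlices <- function(processed, roi, phase) {
  list(
    tfts = lapply(processed, function(p) p[[roi]][[phase]]$tfr),
    scheds = lapply(processed, function(p) p[[roi]][[phase]]$schedule),
    labels = lapply(processed, function(p) {
      p[[roi]][[phase]]$schedule$valence
    }))
}

#' Theta-band condition contrast over a processed cohort
#'
#' CS+ vs CS- (current valence) time-frequency contrast in one ROI and
#' phase, cluster-corrected.
#'
#' @param processed list of \code{\link{processParticipant}} results.
#' @param roi ROI name.
#' @param phase phase name (default "extinction").
#' @param ... passed to \code{\link{tfConditionContrast}}.
#' @return see \code{\link{tfConditionContrast}}.
#' @export
cohortThetaContrast <- function(processed, roi, phase = "extinction", ...) {
  sl <- .cohortSlices(processed, roi, phase)
  tfConditionContrast(sl$tfts, sl$labels, ...)
}

#' Per-participant pairwise similarities over a processed cohort
#'
#' Builds sliding-window feature vectors and pairwise Spearman similarity
#' arrays for every participant of a processed cohort; the result can be
#' fed to both \code{\link{cohortItemStability}} and
#' \code{\link{cohortContextSpecificity}} to avoid recomputation.
#'
#' @param processed list of \code{\link{processParticipant}} results.
#' @param roi ROI name.
#' @param phase phase name.
#' @param ... passed to \code{\link{buildFeatureVectors}}.
#' @return list with \code{sims} (per participant) and \code{scheds}.
#' @export
cohortSimilarities <- function(processed, roi, phase = "extinction", ...) {
  sl <- .cohortSlices(processed, roi, phase)
  sims <- lapply(sl$tfts, function(tf) {
    pairwiseSpearman(buildFeatureVectors(tf, ...))
  })
  list(sims = sims, scheds = sl$scheds)
}

#' Item-stability contrast over a processed cohort
#'
#' Builds cue-locked sliding-window feature vectors and pairwise Spearman
#' similarities per participant, then runs the CS+ vs CS- item stability
#' contrast.
#'
#' @param processed list of \code{\link{processParticipant}} results.
#' @param roi ROI name.
#' @param phase phase (default "extinction").
#' @param nPerm,seed permutation settings.
#' @param sims optional precomputed \code{\link{cohortSimilarities}}.
#' @param ... passed to \code{\link{itemStabilityContrast}}.
#' @return see \code{\link{itemStabilityContrast}}.
#' @export
cohortItemStability <- function(processed, roi, phase = "extinction",
                                nPerm = 1000, seed = 1, sims = NULL, ...) {
  if (is.null(sims)) sims <- cohortSimilarities(processed, roi, phase)
  itemStabilityContrast(sims$sims, sims$scheds, nPerm = nPerm, seed = seed,
                        ...)
}

#' Context-specificity contrast over a processed cohort
#'
#' @inheritParams cohortItemStability
#' @param ... passed to \code{\link{contextSpecificityContrast}}.
#' @return see \code{\link{contextSpecificityContrast}}.
#' @export
cohortContextSpecificity <- function(processed, roi, phase = "extinction",
                                     nPerm = 1000, seed = 1, sims = NULL,
                                     ...) {
  if (is.null(sims)) sims <- cohortSimilarities(processed, roi, phase)
  contextSpecificityContrast(sims$sims, sims$scheds, nPerm = nPerm,
                             seed = seed, ...)
}

#' Run the full simulated-experiment pipeline
#'
#' Simulates a cohort under the configured design and generator, processes
#' every participant, and runs the analysis chain: behavioural
#' learning-curve and repeated-measures ANOVA, the theta condition
#' contrast, item stability, context specificity and (optionally) the
#' cross-phase reinstatement block. Deterministic for a fixed config.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory; the report is written as JSON
#'   and the behavioural/metric tables as TSV.
#' @return report list with provenance (config hash, package version,
#'   seeds) and per-analysis summaries.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  validatePipelineConfig(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  rois <- unique(unlist(config$analysisRois))
  processed <- stage("simulate+preprocess", simulateCohort(
    config$nParticipants, config$design, config$generator,
    seed = config$seed, phases = config$phases,
    process = function(part) {
      processParticipant(part, rois = rois,
                         tfrWindow = config$tfrWindow,
                         timeStep = config$timeStep,
                         minTrials = config$minTrials)
    }))

  report <- list(provenance = list(
    configHash = .configHash(config),
    package = as.character(utils::packageVersion("extinctRSA")),
    seed = config$seed,
    nParticipants = config$nParticipants))

  # behaviour
  report$behaviour <- stage("behaviour", {
    ratings <- do.call(rbind, lapply(seq_along(processed), function(i) {
      cbind(participant = i, processed[[i]]$ratings)
    }))
    ratings$cue <- ratings$role
    anova <- if (length(unique(ratings$phase)) >= 2) rmAnova2way(ratings)
    lcPhase <- if ("extinction" %in% ratings$phase) "extinction" else
      unique(ratings$phase)[1]
    lc <- learningCurveTest(ratings, lcPhase, c("CS++", "CS+-"),
                            nPerm = config$nPerm,
                            seed = .childSeed(config$seed, 11))
    list(anova = anova$effects, posthoc = anova$posthoc,
         extinctionOnsets = lc$onsets)
  })

  report$theta <- stage("theta-contrast", {
    res <- cohortThetaContrast(processed, config$analysisRois$theta,
                               freqRange = config$freqRangeTheta,
                               nPerm = config$nPerm,
                               minTrials = config$minTrials,
                               seed = .childSeed(config$seed, 12))
    list(clusters = clusters(res$test), nIncluded = res$nIncluded)
  })

  report$itemStability <- stage("item-stability", {
    res <- cohortItemStability(processed, config$analysisRois$item,
                               nPerm = config$nPerm,
                               minTrials = config$minTrials,
                               seed = .childSeed(config$seed, 13))
    list(clusters = clusters(res$test), nIncluded = res$nIncluded)
  })

  report$contextSpecificity <- stage("context-specificity", {
    res <- cohortContextSpecificity(processed,
                                    config$analysisRois$context,
                                    nPerm = config$nPerm,
                                    minTrials = config$minTrials,
                                    seed = .childSeed(config$seed, 14))
    list(clusters = clusters(res$test), nIncluded = res$nIncluded)
  })

  if (config$reinstatement &&
      all(c("acquisition", "extinction", "test") %in% config$phases)) {
    report$reinstatement <- stage("reinstatement", {
      roi <- config$analysisRois$item
      ctxRoi <- config$analysisRois$context
      recs <- list(); ctx <- c(); rr <- list(); rat <- list()
      for (i in seq_along(processed)) {
        p <- processed[[i]]
        pat <- lapply(c("acquisition", "extinction", "test"),
                      function(ph) buildFeatureVectors(p[[roi]][[ph]]$tfr))
        names(pat) <- c("acquisition", "extinction", "test")
        simAT <- crossPhaseSimilarity(pat$acquisition, pat$test)
        simET <- crossPhaseSimilarity(pat$extinction, pat$test)
        schA <- p[[roi]]$acquisition$schedule
        schE <- p[[roi]]$extinction$schedule
        schT <- p[[roi]]$test$schedule
        recs[[i]] <- reinstatementRecord(simAT, simET, schA, schE, schT,
                                         window = config$contextWindow)
        # lPFC context specificity, window-averaged
        simC <- pairwiseSpearman(
          buildFeatureVectors(p[[ctxRoi]]$extinction$tfr))
        stc <- singleTrialContextSpecificity(
          simC, p[[ctxRoi]]$extinction$schedule)
        cols <- attr(stc, "centers") >= config$contextWindow[1] &
          attr(stc, "centers") <= config$contextWindow[2]
        ctx[i] <- mean(stc[, cols], na.rm = TRUE)
        rr[[i]] <- trialReinstatement(simET, schE, schT,
                                      window = config$itemWindow)
        rat[[i]] <- {
          r <- p$ratings
          r <- r[r$phase == "test", ]
          r$rating[match(schT$index, r$index)]
        }
      }
      dr <- differentialReinstatement(recs)
      wide <- tapply(dr$byParticipant$reinst,
                     list(dr$byParticipant$participant,
                          dr$byParticipant$role), mean)
      cvr <- contextVsReinstatementCorrelation(ctx, wide)
      rvr <- reinstatementVsRatings(rr, rat)
      list(roleMeans = dr$roleMeans, contextVsReinst = cvr,
           ratingsCoupling = rvr$byRole)
    })
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report, file.path(outDir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  }
  report
}
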