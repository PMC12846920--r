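# Three-phase ABC experimental schedules: pseudo-randomized cue sequences
# under a run-length cap, balanced context assignment, and 50% partial
# reinforcement of CS+ cues.

.ROLES <- c("CS++", "CS+-", "CS--")

#' Experimental design configuration
#'
#' Parameters of the three-phase (acquisition, extinction, test) ABC
#' conditioning design: 3 cue identities presented 24 times per learning
#' phase and 16 times at test, 50% US reinforcement of CS+ cues, 4/4/8
#' context videos per phase, and a cap of 3 consecutive presentations of the
#' same cue.
#'
#' @param nCues number of cue identities (3).
#' @param repsLearning presentations per cue during acquisition/extinction
#'   (24).
#' @param repsTest presentations per cue during test (16).
#' @param reinforcementRate fraction of CS+ trials carrying the aversive US
#'   (0.5); \code{reinforcementRate * repsLearning} must be an integer.
#' @param nContexts per-phase context counts, named or ordered
#'   (acquisition, extinction, test) = (4, 4, 8).
#' @param maxRunLength maximum consecutive same-cue presentations (3).
#' @param timing named durations in seconds: fixation 0.5, video-alone 2.0,
#'   cue 1.75, us 1.0, response window, inter-trial interval.
#' @return a list of class \code{"DesignConfig"}.
#' @export
designConfig <- function(nCues = 3, repsLearning = 24, repsTest = 16,
                         reinforcementRate = 0.5,
                         nContexts = c(acquisition = 4, extinction = 4,
                                       test = 8),
                         maxRunLength = 3,
                         timing = c(fixation = 0.5, video = 2.0, cue = 1.75,
                                    us = 1.0, response = 2.0, iti = 1.5)) {
  nReinforced <- reinforcementRate * repsLearning
  if (abs(nReinforced - round(nReinforced)) > 1e-9)
    stop("reinforcementRate * repsLearning must be an integer")
  if (maxRunLength < 1) stop("maxRunLength must be >= 1")
  if (length(nContexts) != 3) stop("nContexts must give 3 per-phase counts")
  names(nContexts) <- c("acquisition", "extinction", "test")
  cfg <- list(nCues = nCues, repsLearning = repsLearning,
              repsTest = repsTest, reinforcementRate = reinforcementRate,
              nContexts = nContexts, maxRunLength = maxRunLength,
              timing = timing)
  class(cfg) <- "DesignConfig"
  cfg
}

# Cue sequence with each cue appearing reps times and no run longer than
# maxRun: rejection sampling with a retry cap, then constrained backtracking.
.cueSequence <- function(nCues, reps, maxRun, retries = 10000) {
  base <- rep(seq_len(nCues), each = reps)
  runsOk <- function(x) {
    r <- rle(x)
    all(r$lengths <= maxRun)
  }
  for (i in seq_len(retries)) {
    s <- sample(base)
    if (runsOk(s)) return(s)
  }
  # backtracking fallback: place trials greedily, preferring the most
  # abundant remaining cue that does not violate the run cap
  remaining <- rep(reps, nCues)
  out <- integer(nCues * reps)
  run <- 0L; last <- 0L
  for (k in seq_along(out)) {
    ok <- which(remaining > 0 & !(seq_len(nCues) == last & run >= maxRun))
    if (!length(ok)) stop("run-length constraint unsatisfiable")
    pick <- ok[sample.int(length(ok), 1, prob = remaining[ok])]
    out[k] <- pick
    if (pick == last) run <- run + 1L else { last <- pick; run <- 1L }
    remaining[pick] <- remaining[pick] - 1L
  }
  out
}

# Balanced context assignment: within each cue, every context of the phase
# pool appears equally often (reps / nContexts must be an integer under the
# default design), in randomized order.
.contextAssignment <- function(cueSeq, nCues, reps, pool) {
  ctx <- integer(length(cueSeq))
  per <- reps / length(pool)
  if (abs(per - round(per)) > 1e-9)
    stop("reps per cue must be a multiple of the context-pool size")
  for (c in seq_len(nCues)) {
    idx <- which(cueSeq == c)
    ctx[idx] <- sample(rep(pool, each = per))
  }
  ctx
}

.currentValence <- function(role, phase) {
  switch(phase,
    acquisition = ifelse(role == "CS--", "CS-", "CS+"),
    extinction = ifelse(role == "CS++", "CS+", "CS-"),
    test = ifelse(role == "CS++", "CS+", "CS-"))
}

#' Generate one phase of the experimental schedule
#'
#' Draws a pseudo-randomized trial sequence for one phase satisfying the
#' design invariants: exact per-cue counts, no more than
#' \code{maxRunLength} consecutive same-cue trials, balanced context
#' assignment (each phase context equally often per cue), and exactly
#' \code{reinforcementRate * reps} aversive US deliveries per CS+ cue in the
#' learning phases (none at test). Deterministic for a fixed seed.
#'
#' @param phase \code{"acquisition"}, \code{"extinction"} or \code{"test"}.
#' @param design a \code{\link{designConfig}}.
#' @param counterbalance named integer vector mapping roles
#'   (\code{"CS++"}, \code{"CS+-"}, \code{"CS--"}) to cue ids (a bijection).
#' @param seed RNG seed.
#' @param contextPool context ids for this phase (defaults to the standard
#'   disjoint pools 1:4 / 5:8 / 9:16).
#' @return a data.frame of class \code{"TrialSchedule"}, one row per trial,
#'   with columns phase, index, cue_id, role, valence, context_id, us and
#'   within-trial onsets (s); design, seed and counterbalance are stored as
#'   attributes.
#' @export
generatePhaseSchedule <- function(phase, design = designConfig(),
                                  counterbalance = c("CS++" = 1, "CS+-" = 2,
                                                     "CS--" = 3),
                                  seed = 1, contextPool = NULL) {
  phase <- match.arg(phase, c("acquisition", "extinction", "test"))
  if (length(unique(counterbalance)) != design$nCues ||
      !setequal(names(counterbalance), .ROLES))
    stop("counterbalance must be a bijection of roles onto cue ids")
  set.seed(seed)
  reps <- if (phase == "test") design$repsTest else design$repsLearning
  nCtx <- design$nContexts[[phase]]
  if (is.null(contextPool)) {
    offset <- c(acquisition = 0, extinction = design$nContexts[[1]],
                test = design$nContexts[[1]] + design$nContexts[[2]])[[phase]]
    contextPool <- offset + seq_len(nCtx)
  }
  cueSeq <- .cueSequence(design$nCues, reps, design$maxRunLength)
  ctx <- .contextAssignment(cueSeq, design$nCues, reps, contextPool)
  roleOf <- stats::setNames(names(counterbalance), counterbalance)
  role <- unname(roleOf[as.character(cueSeq)])
  valence <- .currentValence(role, phase)

  us <- logical(length(cueSeq))
  if (phase != "test") {
    nRein <- round(design$reinforcementRate * reps)
    for (c in seq_len(design$nCues)) {
      idx <- which(cueSeq == c)
      if (valence[idx[1]] == "CS+") us[idx[sample.int(reps, nRein)]] <- TRUE
    }
  }
  tm <- design$timing
  sched <- data.frame(
    phase = phase,
    index = seq_along(cueSeq),
    cue_id = cueSeq,
    role = role,
    valence = valence,
    context_id = ctx,
    us = us,
    onset_fixation = 0,
    onset_video = unname(tm["fixation"]),
    onset_cue = unname(tm["fixation"] + tm["video"]),
    onset_us = unname(tm["fixation"] + tm["video"] + tm["cue"]),
    duration = unname(sum(tm[c("fixation", "video", "cue", "us",
                               "response")]))
  )
  attr(sched, "design") <- design
  attr(sched, "seed") <- seed
  attr(sched, "counterbalance") <- counterbalance
  class(sched) <- c("TrialSchedule", "data.frame")
  sched
}

#' Generate the full three-phase experiment
#'
#' Draws acquisition, extinction and test schedules with a (optionally
#' random) counterbalance of cue ids to roles, consistent roles across
#' phases, disjoint per-phase context pools, and the design's US budget
#' (with defaults: 24 + 12 = 36 aversive US deliveries in total).
#'
#' @param design a \code{\link{designConfig}}.
#' @param seed RNG seed (drives the counterbalance and all three phases).
#' @param counterbalance optional fixed role -> cue id assignment; random
#'   when NULL.
#' @return list with elements \code{acquisition}, \code{extinction},
#'   \code{test} (TrialSchedules) and \code{counterbalance}.
#' @export
generateExperiment <- function(design = designConfig(), seed = 1,
                               counterbalance = NULL) {
  set.seed(seed)
  if (is.null(counterbalance)) {
    counterbalance <- stats::setNames(sample(design$nCues), .ROLES)
  }
  phases <- c("acquisition", "extinction", "test")
  out <- lapply(seq_along(phases), function(i) {
    generatePhaseSchedule(phases[i], design, counterbalance,
                          seed = .childSeed(seed, i))
  })
  names(out) <- phases
  out$counterbalance <- counterbalance
  out
}

#' Validate a trial schedule against the design invariants
#'
#' Checks per-cue trial counts, the run-length cap, the reinforcement tally
#' (including the no-US-at-test rule), context-pool membership and context
#' balance. Returns a zero-length character vector iff the schedule is
#' valid.
#'
#' @param schedule a TrialSchedule.
#' @return character vector of violation messages (empty if valid).
#' @export
validateSchedule <- function(schedule) {
  design <- attr(schedule, "design")
  phase <- schedule$phase[1]
  reps <- if (phase == "test") design$repsTest else design$repsLearning
  v <- character()

  cnt <- table(schedule$cue_id)
  if (length(cnt) != design$nCues || any(cnt != reps))
    v <- c(v, sprintf("per-cue counts not all %d", reps))

  runs <- rle(schedule$cue_id)
  if (any(runs$lengths > design$maxRunLength))
    v <- c(v, sprintf("run length > %d", design$maxRunLength))

  if (phase == "test") {
    if (any(schedule$us)) v <- c(v, "US in test phase")
  } else {
    nRein <- round(design$reinforcementRate * reps)
    for (c in unique(schedule$cue_id)) {
      rows <- schedule[schedule$cue_id == c, ]
      expect <- if (rows$valence[1] == "CS+") nRein else 0
      if (sum(rows$us) != expect)
        v <- c(v, sprintf("cue %s: %d US deliveries, expected %d",
                          c, sum(rows$us), expect))
    }
  }

  nCtx <- design$nContexts[[phase]]
  if (length(unique(schedule$context_id)) != nCtx)
    v <- c(v, sprintf("expected %d unique contexts", nCtx))
  tab <- table(schedule$cue_id, schedule$context_id)
  if (max(tab) - min(tab) > 1)
    v <- c(v, "context counts per cue unbalanced beyond +/-1")

  badVal <- schedule$valence != .currentValence(schedule$role, phase)
  if (any(badVal)) v <- c(v, "valence inconsistent with role x phase")
  v
}

#' Write / read a schedule as TSV
#'
#' @param schedule a TrialSchedule.
#' @param path output file path.
#' @return (write) the path, invisibly; (read) a data.frame.
#' @export
writeScheduleTSV <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScheduleTSV
#' @export
readScheduleTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
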