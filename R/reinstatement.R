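# Cross-phase reinstatement: similarity of test-phase activity patterns to
# same-item patterns from acquisition or extinction, the differential
# reinstatement metric REINST = REINST_ACQ - REINST_EXT, and its
# brain-behaviour / brain-brain correlates.

#' Cross-phase pattern similarity
#'
#' Spearman correlation between every trial of an earlier phase and every
#' test trial at each matching window center (the two pattern series must
#' share the feature-vector definition: same ROI channels and grid).
#'
#' @param patternsX \linkS4class{PatternSeries} of the earlier phase
#'   (acquisition or extinction).
#' @param patternsTest \linkS4class{PatternSeries} of the test phase.
#' @return numeric array trialsX x trialsTest x centers with attribute
#'   \code{centers}.
#' @export
crossPhaseSimilarity <- function(patternsX, patternsTest) {
  if (dim(patternsX@features)[2] != dim(patternsTest@features)[2])
    stop("pattern series differ in feature dimension")
  if (length(patternsX@centers) != length(patternsTest@centers))
    stop("pattern series differ in window centers")
  nC <- length(patternsX@centers)
  out <- array(NA_real_,
               c(dim(patternsX@features)[1],
                 dim(patternsTest@features)[1], nC))
  for (k in seq_len(nC)) {
    rx <- .rankScale(t(patternsX@features[, , k]))
    rt <- .rankScale(t(patternsTest@features[, , k]))
    out[, , k] <- crossprod(rx, rt)
  }
  attr(out, "centers") <- patternsX@centers
  out
}

#' Participant-level reinstatement record
#'
#' Averages Fisher-z cross-phase similarities over same-item trial pairs
#' and over the window centers of a configured analysis window, separately
#' per cue role, yielding REINST_ACQ, REINST_EXT and their difference
#' REINST = REINST_ACQ - REINST_EXT (positive values: predominant
#' reinstatement of the fear memory trace; negative: of the extinction
#' trace).
#'
#' @param simAcqTest,simExtTest arrays from
#'   \code{\link{crossPhaseSimilarity}} (acquisition-test and
#'   extinction-test).
#' @param schedAcq,schedExt,schedTest the phase TrialSchedules (rows
#'   matching the similarity axes).
#' @param window window-center range in seconds (default the lPFC context
#'   specificity window c(0.8, 1.15)).
#' @return data.frame: role, reinstAcq, reinstExt, reinst (Fisher-z scale).
#' @export
reinstatementRecord <- function(simAcqTest, simExtTest, schedAcq, schedExt,
                                schedTest, window = c(0.8, 1.15)) {
  centers <- attr(simAcqTest, "centers")
  cols <- which(centers >= window[1] & centers <= window[2])
  if (!length(cols)) stop("window contains no window centers")
  phaseMean <- function(sim, schedX) {
    sX <- as.data.frame(schedX); sT <- as.data.frame(schedTest)
    out <- c()
    for (role in sort(unique(sT$role))) {
      iX <- which(sX$role == role)
      iT <- which(sT$role == role)
      same <- outer(sX$cue_id[iX], sT$cue_id[iT], `==`)
      vals <- c()
      for (k in cols) {
        z <- fisherZ(sim[iX, iT, k, drop = FALSE][, , 1])
        vals <- c(vals, z[same])
      }
      out[role] <- mean(vals, na.rm = TRUE)
    }
    out
  }
  acq <- phaseMean(simAcqTest, schedAcq)
  ext <- phaseMean(simExtTest, schedExt)
  data.frame(role = names(acq), reinstAcq = unname(acq),
             reinstExt = unname(ext),
             reinst = unname(acq) - unname(ext), row.names = NULL)
}

#' Differential reinstatement across participants
#'
#' Stacks per-participant reinstatement records and returns per-role
#' averages of REINST = REINST_ACQ - REINST_EXT (subtraction on the
#' Fisher-z scale).
#'
#' @param records list of data.frames from
#'   \code{\link{reinstatementRecord}}.
#' @return list with \code{byParticipant} (long data.frame with
#'   participant ids) and \code{roleMeans}.
#' @export
differentialReinstatement <- function(records) {
  long <- do.call(rbind, lapply(seq_along(records), function(i) {
    cbind(participant = i, records[[i]])
  }))
  roleMeans <- c(tapply(long$reinst, long$role, mean, na.rm = TRUE))
  list(byParticipant = long, roleMeans = roleMeans)
}

#' Across-participant correlation of context specificity and reinstatement
#'
#' Spearman correlation, across participants, of extinction-phase lPFC
#' context specificity (window-averaged) with differential reinstatement in
#' a target ROI, separately per cue role.
#'
#' @param ctxSpec numeric vector of per-participant context specificity.
#' @param reinst matrix or data.frame participants x roles of REINST
#'   values (column names = roles).
#' @return data.frame: role, n, rho, p (from \code{cor.test}, two-sided).
#' @export
contextVsReinstatementCorrelation <- function(ctxSpec, reinst) {
  reinst <- as.matrix(reinst)
  out <- do.call(rbind, lapply(colnames(reinst), function(role) {
    ok <- is.finite(ctxSpec) & is.finite(reinst[, role])
    if (sum(ok) < 5)
      stop("fewer than 5 participants with both measures for ", role)
    ct <- suppressWarnings(
      stats::cor.test(ctxSpec[ok], reinst[ok, role], method = "spearman"))
    data.frame(role = role, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value)
  }))
  rownames(out) <- NULL
  out
}

#' Time-resolved context-specificity vs reinstatement correlation
#'
#' Correlates the fixed per-participant context-specificity value against
#' the REINST time course at every window center, with 1D cluster
#' correction built by permuting participants.
#'
#' @param ctxSpec numeric vector (participants).
#' @param reinstCourse matrix participants x centers of REINST values.
#' @param centers window-center times.
#' @param nPerm,clusterAlpha,seed permutation settings.
#' @return list with \code{rho} per center and \code{test}.
#' @export
contextVsReinstatementTimecourse <- function(ctxSpec, reinstCourse,
                                             centers, nPerm = 1000,
                                             clusterAlpha = 0.05,
                                             seed = 1) {
  ok <- is.finite(ctxSpec) & apply(is.finite(reinstCourse), 1, all)
  if (sum(ok) < 5) stop("fewer than 5 complete participants")
  x <- ctxSpec[ok]; y <- reinstCourse[ok, , drop = FALSE]
  n <- length(x)
  rx <- .rankScale(matrix(x, ncol = 1))
  ry <- .rankScale(y)
  rhoObs <- as.numeric(crossprod(rx, ry))
  set.seed(seed)
  nC <- ncol(y)
  zPerm <- matrix(0, nPerm, nC)
  for (p in seq_len(nPerm)) {
    zPerm[p, ] <- fisherZ(as.numeric(
      crossprod(rx[sample.int(n), , drop = FALSE], ry)))
  }
  # cluster-forming threshold on the Fisher-z scale: |z| with two-sided
  # alpha under the permutation distribution per bin
  zObs <- fisherZ(rhoObs)
  thr <- stats::quantile(abs(zPerm), 1 - clusterAlpha)
  nullMax <- .permMaxClusterMassC(as.numeric(zPerm), c(nPerm, 1L, nC),
                                  thr)
  test <- .makeClusterResult(matrix(zObs, 1, nC), nullMax, thr, nPerm,
                             clusterAlpha,
                             scheme = "participant-shuffle", seed = seed,
                             rowValues = 1, colValues = centers)
  list(rho = rhoObs, test = test, centers = centers, n = n)
}

#' Single-trial extinction-to-test reinstatement
#'
#' For every test trial: the mean Fisher-z similarity to extinction trials
#' of the same item minus the mean similarity to extinction trials of
#' different items, averaged over the window centers of the configured
#' analysis window (default the TMP item-stability window 0.65-1 s).
#'
#' @param simExtTest array from \code{\link{crossPhaseSimilarity}}
#'   (extinction x test).
#' @param schedExt,schedTest the phase TrialSchedules.
#' @param window window-center range in seconds (default c(0.65, 1)).
#' @return numeric vector per test trial, with attribute \code{role}.
#' @export
trialReinstatement <- function(simExtTest, schedExt, schedTest,
                               window = c(0.65, 1)) {
  centers <- attr(simExtTest, "centers")
  cols <- which(centers >= window[1] & centers <= window[2])
  if (!length(cols)) stop("window contains no window centers")
  sE <- as.data.frame(schedExt); sT <- as.data.frame(schedTest)
  z <- fisherZ(simExtTest[, , cols, drop = FALSE])
  zw <- apply(z, c(1, 2), mean, na.rm = TRUE)
  same <- outer(sE$cue_id, sT$cue_id, `==`)
  sameMean <- colSums(zw * same) / colSums(same)
  diffMean <- colSums(zw * !same) / colSums(!same)
  out <- sameMean - diffMean
  attr(out, "role") <- sT$role
  out
}

#' Group test of reinstatement-rating coupling
#'
#' Per participant and cue role, Spearman-correlates single-trial
#' extinction-to-test reinstatement with the subjective safety ratings of
#' the responded test trials, optionally excluding trials whose
#' reinstatement deviates more than \code{outlierSD} SDs from the
#' participant mean; Fisher-z rho values are then tested against zero at
#' the group level per role.
#'
#' @param reinstList list over participants of per-test-trial
#'   reinstatement vectors (attribute \code{role} as from
#'   \code{\link{trialReinstatement}}).
#' @param ratingsList list over participants of test-phase rating vectors
#'   aligned with the reinstatement vectors (NA = no response).
#' @param outlierSD NULL (no exclusion) or a positive number (e.g. 2).
#' @param minTrials minimum valid trials per role (default 4; the stricter
#'   variant uses 8).
#' @return list with \code{byRole} (data.frame: role, n, t, df, p) and
#'   \code{rho} (participants x roles).
#' @export
reinstatementVsRatings <- function(reinstList, ratingsList,
                                   outlierSD = NULL, minTrials = 4) {
  roles <- sort(unique(unlist(lapply(reinstList, attr, "role"))))
  nP <- length(reinstList)
  rho <- matrix(NA_real_, nP, length(roles),
                dimnames = list(NULL, roles))
  for (i in seq_len(nP)) {
    r <- reinstList[[i]]
    rt <- ratingsList[[i]]
    rl <- attr(r, "role")
    for (role in roles) {
      sel <- rl == role & !is.na(rt) & is.finite(r)
      x <- r[sel]; y <- rt[sel]
      if (!is.null(outlierSD) && length(x) > 2) {
        keep <- abs(x - mean(x)) <= outlierSD * stats::sd(x)
        x <- x[keep]; y <- y[keep]
      }
      if (length(x) < minTrials) next
      if (stats::sd(y) == 0 || stats::sd(x) == 0) next  # rho undefined
      rho[i, role] <- stats::cor(x, y, method = "spearman")
    }
  }
  byRole <- do.call(rbind, lapply(roles, function(role) {
    v <- rho[, role]
    v <- v[is.finite(v)]
    if (length(v) < 2)
      return(data.frame(role = role, n = length(v), t = NA_real_,
                        df = NA_real_, p = NA_real_))
    tt <- .safeTTest(fisherZ(v))
    data.frame(role = role, n = length(v), t = tt$t, df = tt$df, p = tt$p)
  }))
  list(byRole = byRole, rho = rho)
}
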