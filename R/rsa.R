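# Contrast-based and single-trial representational similarity analysis:
# spectral-spatial feature vectors in sliding windows, pairwise Spearman
# similarity, item stability and context specificity metrics.

#' Build sliding-window spectral-spatial feature vectors
#'
#' For each 500-ms window (stepped by 50 ms, 90% overlap), frequency-specific
#' z-scored power is averaged over the window per channel x frequency and
#' flattened into one feature vector per trial. Window centers are assigned
#' to the window midpoint (0-500 ms -> 250 ms).
#'
#' @param tft a z-scored \linkS4class{TFRArray}.
#' @param roi optional ROI name(s) selecting channels (default all).
#' @param windowLength window length in seconds (default 0.5).
#' @param step window step in seconds (default 0.05).
#' @param range c(start, end) of the analysis period in the tensor's
#'   (cue-locked) time frame; default the full tensor span.
#' @param lock \code{"cue"} or \code{"video"}; with \code{"video"}, centers
#'   are reported relative to video onset at \code{videoOnset} s in the
#'   cue-locked frame.
#' @param videoOnset video onset in the cue-locked frame (default -2).
#' @return a \linkS4class{PatternSeries}.
#' @export
buildFeatureVectors <- function(tft, roi = NULL, windowLength = 0.5,
                                step = 0.05, range = NULL,
                                lock = c("cue", "video"),
                                videoOnset = -2) {
  lock <- match.arg(lock)
  if (tft@normalization != "zscored")
    stop("feature vectors require z-scored power")
  chSel <- if (is.null(roi)) seq_len(nrow(tft@channelInfo)) else
    which(tft@channelInfo$roi %in% roi)
  if (!length(chSel)) stop("ROI has no channels")
  tms <- tft@times
  if (is.null(range)) range <- c(min(tms), max(tms) )
  eps <- 1e-9
  if (range[1] < min(tms) - eps || range[2] > max(tms) + eps)
    stop("requested window range extends beyond the decomposed period")
  starts <- seq(range[1], range[2] - windowLength + eps, by = step)
  if (!length(starts)) stop("no complete window fits the range")
  d <- dim(tft@power)
  nW <- length(starts)
  feat <- array(NA_real_, c(d[1], length(chSel) * d[3], nW))
  for (w in seq_len(nW)) {
    sel <- which(tms >= starts[w] - eps & tms < starts[w] + windowLength - eps)
    pw <- tft@power[, chSel, , sel, drop = FALSE]
    if (anyNA(pw)) stop("window overlaps edge-invalid bins")
    feat[, , w] <- matrix(apply(pw, c(1, 2, 3), mean), nrow = d[1])
  }
  centers <- starts + windowLength / 2
  if (lock == "video") centers <- centers - videoOnset
  new("PatternSeries", features = feat, centers = centers, lock = lock,
      trialInfo = tft@trialInfo)
}

#' Pairwise Spearman similarity of trial patterns
#'
#' Spearman rank correlation between the feature vectors of every pair of
#' trials at each matching window center (average-rank tie handling).
#' Pairs involving a zero-variance vector are recorded as NA (missing), and
#' the diagonal is NA by convention (a trial is never compared to itself).
#'
#' @param patterns a \linkS4class{PatternSeries}.
#' @return numeric array trials x trials x windows with attributes
#'   \code{centers}, \code{lock} and \code{metric}.
#' @export
pairwiseSpearman <- function(patterns) {
  d <- dim(patterns@features)
  if (d[1] < 2) stop("need at least 2 trials")
  if (d[2] < 3) stop("feature vectors must have length >= 3")
  out <- array(NA_real_, c(d[1], d[1], d[3]))
  for (w in seq_len(d[3])) {
    r <- .rankScale(t(patterns@features[, , w]))
    rho <- crossprod(r)
    diag(rho) <- NA_real_
    out[, , w] <- rho
  }
  attr(out, "centers") <- patterns@centers
  attr(out, "lock") <- patterns@lock
  attr(out, "metric") <- "spearman"
  out
}

# Fisher-z similarity stack with NA->0 values plus validity mask.
.zstack <- function(sim) {
  z <- fisherZ(sim)
  m <- is.finite(z) * 1
  z[!is.finite(z)] <- 0
  list(z = z, m = m)
}

# quadform diag(V' A V) for each column of V: colSums(V * (A %*% V))
.quadDiag <- function(a, v) colSums(v * (a %*% v))

# Per-item mean Fisher-z similarity series for a given cue assignment.
# z, m: T x T x C; cueIds: per-trial cue assignment. Returns items x centers.
.itemStabilitySeries <- function(z, m, cueIds) {
  cues <- sort(unique(cueIds))
  nC <- dim(z)[3]
  out <- matrix(NA_real_, length(cues), nC,
                dimnames = list(as.character(cues), NULL))
  for (ci in seq_along(cues)) {
    v <- matrix(as.numeric(cueIds == cues[ci]), ncol = 1)
    for (k in seq_len(nC)) {
      sZ <- .quadDiag(z[, , k], v)
      sM <- .quadDiag(m[, , k], v)
      out[ci, k] <- if (sM > 0) sZ / sM else NA_real_
    }
  }
  out
}

#' Item stability contrast (CS+ vs CS-)
#'
#' Item stability is the average Fisher-z Spearman similarity of a cue's
#' patterns across its repeated presentations (within-item pairs only,
#' never averaging patterns across repetitions). Because one contingency
#' class holds two items and the other one, stability is computed per item
#' and the two same-contingency items are averaged before contrasting.
#' Group inference is a paired t test per window center, corrected by 1D
#' cluster-based permutation with cue labels shuffled across trials within
#' each participant.
#'
#' @param simList list over participants of similarity arrays from
#'   \code{\link{pairwiseSpearman}} (same centers).
#' @param schedList list over participants of the phase TrialSchedules
#'   (rows matching the similarity trial axis).
#' @param nPerm,clusterAlpha,seed permutation settings.
#' @param minTrials per-condition minimum (default 8); participants below
#'   it are dropped.
#' @return list with \code{centers}, \code{csPlus} / \code{csMinus}
#'   (participants x centers Fisher-z stability), \code{diff},
#'   \code{perItem}, \code{test} (\linkS4class{ClusterTestResult}) and
#'   \code{nIncluded}.
#' @export
itemStabilityContrast <- function(simList, schedList, nPerm = 1000,
                                  clusterAlpha = 0.05, seed = 1,
                                  minTrials = 8) {
  set.seed(seed)
  nP <- length(simList)
  centers <- attr(simList[[1]], "centers")
  nC <- length(centers)
  keep <- logical(nP)
  plusSer <- list(); minusSer <- list(); perItem <- list()
  permDiff <- list()
  for (i in seq_len(nP)) {
    sch <- as.data.frame(schedList[[i]])
    tb <- table(sch$valence)
    if (length(tb) < 2 || any(tb < minTrials)) next
    keep[i] <- TRUE
    st <- .zstack(simList[[i]])
    cueIds <- sch$cue_id
    cueVal <- tapply(sch$valence, sch$cue_id, function(x) x[1])
    ser <- .itemStabilitySeries(st$z, st$m, cueIds)
    valOf <- cueVal[rownames(ser)]
    avg <- function(s, val) {
      rows <- which(valOf == val)
      if (length(rows) == 1) s[rows, ] else colMeans(s[rows, , drop = FALSE])
    }
    plusSer[[i]] <- avg(ser, "CS+")
    minusSer[[i]] <- avg(ser, "CS-")
    perItem[[i]] <- ser

    # permutation null: shuffle the cue assignment across trials.
    # Batched: per cue an indicator matrix over permutations, stability via
    # the quadratic form diag(V' Z V) / diag(V' M V).
    cues <- sort(unique(cueIds))
    nT <- length(cueIds)
    permLab <- vapply(seq_len(nPerm), function(p) sample(cueIds),
                      numeric(nT))
    plusAcc <- matrix(0, nPerm, nC); minusAcc <- matrix(0, nPerm, nC)
    nPlus <- sum(valOf == "CS+"); nMinus <- sum(valOf == "CS-")
    for (ci in seq_along(cues)) {
      v <- (permLab == cues[ci]) * 1
      isPlus <- valOf[as.character(cues[ci])] == "CS+"
      for (k in seq_len(nC)) {
        sZ <- colSums(v * (st$z[, , k] %*% v))
        sM <- colSums(v * (st$m[, , k] %*% v))
        val <- ifelse(sM > 0, sZ / sM, 0)
        if (isPlus) plusAcc[, k] <- plusAcc[, k] + val / nPlus
        else minusAcc[, k] <- minusAcc[, k] + val / nMinus
      }
    }
    permDiff[[i]] <- plusAcc - minusAcc
  }
  if (sum(keep) < 2) stop("fewer than 2 includable participants")
  plusMat <- do.call(rbind, plusSer[keep])
  minusMat <- do.call(rbind, minusSer[keep])
  diffMat <- plusMat - minusMat
  tObs <- .oneSampleT(diffMat)
  nIncl <- sum(keep)
  s1 <- Reduce(`+`, permDiff[keep])
  s2 <- Reduce(`+`, lapply(permDiff[keep], function(x) x^2))
  mP <- s1 / nIncl
  vP <- pmax(s2 / nIncl - mP^2, 0) * nIncl / (nIncl - 1)
  tPerm <- mP / sqrt(vP / nIncl)
  tPerm[!is.finite(tPerm)] <- 0
  thr <- stats::qt(1 - clusterAlpha / 2, df = nIncl - 1)
  nullMax <- .permMaxClusterMassC(as.numeric(tPerm), c(nPerm, 1L, nC), thr)
  test <- .makeClusterResult(matrix(tObs, 1, nC), nullMax, thr, nPerm,
                             clusterAlpha,
                             scheme = "within-participant-cue-shuffle",
                             seed = seed, rowValues = 1,
                             colValues = centers)
  list(centers = centers, csPlus = plusMat, csMinus = minusMat,
       diff = diffMat, perItem = perItem[keep], test = test,
       nIncluded = nIncl)
}

# Context-specificity series (same - different context mean Fisher z) for a
# given context assignment; returns vector over centers (and pair counts).
.contextSeries <- function(z, m, ctxIds, baseMask) {
  nC <- dim(z)[3]
  ctxs <- sort(unique(ctxIds))
  sameSum <- matrix(0, length(ctxs), nC)
  sameCnt <- matrix(0, length(ctxs), nC)
  out <- numeric(nC)
  cnts <- numeric(nC)
  for (k in seq_len(nC)) {
    zk <- z[, , k] * baseMask
    mk <- m[, , k] * baseMask
    tot <- sum(zk); totCnt <- sum(mk)
    sS <- 0; sC <- 0
    for (ci in seq_along(ctxs)) {
      v <- matrix(as.numeric(ctxIds == ctxs[ci]), ncol = 1)
      sS <- sS + .quadDiag(zk, v)
      sC <- sC + .quadDiag(mk, v)
    }
    dS <- tot - sS; dC <- totCnt - sC
    out[k] <- (if (sC > 0) sS / sC else NA_real_) -
      (if (dC > 0) dS / dC else NA_real_)
    cnts[k] <- sC / 2
  }
  list(series = out, samePairs = cnts)
}

#' Context specificity contrast (same vs different contexts)
#'
#' Context specificity is the mean Fisher-z similarity of same-context trial
#' pairs minus different-context pairs at each window center, computed
#' across all trial-pair combinations (optionally restricted to
#' different-cue pairs to control the cue-identity confound). Group
#' inference is a one-sample t test of the difference against zero per
#' center, corrected by 1D cluster permutation with context labels shuffled
#' across trials within participant.
#'
#' @param simList,schedList,nPerm,clusterAlpha,seed,minTrials as in
#'   \code{\link{itemStabilityContrast}}.
#' @param pairSet \code{"all"} (default) or \code{"different-cue"}.
#' @return list with \code{centers}, \code{diff} (participants x centers),
#'   \code{samePairs}, \code{test} and \code{nIncluded}.
#' @export
contextSpecificityContrast <- function(simList, schedList, nPerm = 1000,
                                       clusterAlpha = 0.05, seed = 1,
                                       minTrials = 8,
                                       pairSet = c("all", "different-cue")) {
  pairSet <- match.arg(pairSet)
  set.seed(seed)
  nP <- length(simList)
  centers <- attr(simList[[1]], "centers")
  nC <- length(centers)
  keep <- logical(nP)
  diffSer <- list(); permDiff <- list(); pairCounts <- list()
  for (i in seq_len(nP)) {
    sch <- as.data.frame(schedList[[i]])
    tb <- table(sch$valence)
    if (length(tb) < 2 || any(tb < minTrials)) next
    keep[i] <- TRUE
    st <- .zstack(simList[[i]])
    nT <- nrow(sch)
    baseMask <- matrix(1, nT, nT)
    if (pairSet == "different-cue")
      baseMask <- baseMask * outer(sch$cue_id, sch$cue_id, `!=`)
    obs <- .contextSeries(st$z, st$m, sch$context_id, baseMask)
    diffSer[[i]] <- obs$series
    pairCounts[[i]] <- obs$samePairs
    # batched context-label permutations (cf. itemStabilityContrast)
    ctxs <- sort(unique(sch$context_id))
    permLab <- vapply(seq_len(nPerm), function(p) sample(sch$context_id),
                      numeric(nT))
    sameS <- matrix(0, nPerm, nC); sameC <- matrix(0, nPerm, nC)
    zMask <- lapply(seq_len(nC), function(k) st$z[, , k] * baseMask)
    mMask <- lapply(seq_len(nC), function(k) st$m[, , k] * baseMask)
    totS <- vapply(zMask, sum, numeric(1))
    totC <- vapply(mMask, sum, numeric(1))
    for (ci in seq_along(ctxs)) {
      v <- (permLab == ctxs[ci]) * 1
      for (k in seq_len(nC)) {
        sameS[, k] <- sameS[, k] + colSums(v * (zMask[[k]] %*% v))
        sameC[, k] <- sameC[, k] + colSums(v * (mMask[[k]] %*% v))
      }
    }
    diffS <- sweep(-sameS, 2, totS, `+`)
    diffC <- sweep(-sameC, 2, totC, `+`)
    pd <- ifelse(sameC > 0, sameS / sameC, 0) -
      ifelse(diffC > 0, diffS / diffC, 0)
    permDiff[[i]] <- pd
  }
  if (sum(keep) < 2) stop("fewer than 2 includable participants")
  diffMat <- do.call(rbind, diffSer[keep])
  nIncl <- sum(keep)
  tObs <- .oneSampleT(diffMat)
  s1 <- Reduce(`+`, permDiff[keep])
  s2 <- Reduce(`+`, lapply(permDiff[keep], function(x) x^2))
  mP <- s1 / nIncl
  vP <- pmax(s2 / nIncl - mP^2, 0) * nIncl / (nIncl - 1)
  tPerm <- mP / sqrt(vP / nIncl)
  tPerm[!is.finite(tPerm)] <- 0
  thr <- stats::qt(1 - clusterAlpha / 2, df = nIncl - 1)
  nullMax <- .permMaxClusterMassC(as.numeric(tPerm), c(nPerm, 1L, nC), thr)
  test <- .makeClusterResult(matrix(tObs, 1, nC), nullMax, thr, nPerm,
                             clusterAlpha,
                             scheme = "within-participant-context-shuffle",
                             seed = seed, rowValues = 1,
                             colValues = centers)
  minPairs <- min(unlist(pairCounts))
  res <- list(centers = centers, diff = diffMat,
              samePairs = pairCounts, test = test, nIncluded = nIncl,
              lowPairCount = minPairs < 2)
  res
}

#' Phase comparison of window-averaged context specificity
#'
#' Paired t test (across participants) of window-averaged context
#' specificity between two phases (e.g. extinction vs acquisition).
#'
#' @param resA,resB results of \code{\link{contextSpecificityContrast}} for
#'   the two phases, same included participants in the same order.
#' @param window c(lo, hi) window-center range in seconds.
#' @return list with t, df, p and the per-phase participant means.
#' @export
contextPhaseComparison <- function(resA, resB, window) {
  sel <- function(r) {
    cols <- r$centers >= window[1] & r$centers <= window[2]
    rowMeans(r$diff[, cols, drop = FALSE])
  }
  a <- sel(resA); b <- sel(resB)
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = a, meanB = b)
}

#' Single-trial item stability
#'
#' For every trial and window center, the mean Fisher-z similarity of the
#' trial's pattern to the patterns of all other presentations of the same
#' item in the phase.
#'
#' @param sim similarity array from \code{\link{pairwiseSpearman}}.
#' @param schedule the phase TrialSchedule (rows matching trials).
#' @return matrix trials x centers with attribute \code{centers}.
#' @export
singleTrialItemStability <- function(sim, schedule) {
  sch <- as.data.frame(schedule)
  st <- .zstack(sim)
  nT <- dim(sim)[1]; nC <- dim(sim)[3]
  sameItem <- outer(sch$cue_id, sch$cue_id, `==`) * 1
  diag(sameItem) <- 0
  out <- matrix(NA_real_, nT, nC)
  for (k in seq_len(nC)) {
    num <- (st$z[, , k] * sameItem) %*% rep(1, nT)
    den <- (st$m[, , k] * sameItem) %*% rep(1, nT)
    out[, k] <- ifelse(den > 0, num / den, NA_real_)
  }
  attr(out, "centers") <- attr(sim, "centers")
  out
}

#' Single-trial context specificity
#'
#' For every trial and window center, the mean Fisher-z similarity to
#' same-context trials minus the mean similarity to different-context
#' trials.
#'
#' @param sim similarity array from \code{\link{pairwiseSpearman}}.
#' @param schedule the phase TrialSchedule.
#' @param pairSet \code{"all"} or \code{"different-cue"}.
#' @return matrix trials x centers with attribute \code{centers}.
#' @export
singleTrialContextSpecificity <- function(sim, schedule,
                                          pairSet = c("all",
                                                      "different-cue")) {
  pairSet <- match.arg(pairSet)
  sch <- as.data.frame(schedule)
  st <- .zstack(sim)
  nT <- dim(sim)[1]; nC <- dim(sim)[3]
  base <- matrix(1, nT, nT)
  diag(base) <- 0
  if (pairSet == "different-cue")
    base <- base * outer(sch$cue_id, sch$cue_id, `!=`)
  sameCtx <- outer(sch$context_id, sch$context_id, `==`) * base
  diffCtx <- (1 - outer(sch$context_id, sch$context_id, `==`)) * base
  out <- matrix(NA_real_, nT, nC)
  ones <- rep(1, nT)
  for (k in seq_len(nC)) {
    sNum <- (st$z[, , k] * sameCtx) %*% ones
    sDen <- (st$m[, , k] * sameCtx) %*% ones
    dNum <- (st$z[, , k] * diffCtx) %*% ones
    dDen <- (st$m[, , k] * diffCtx) %*% ones
    out[, k] <- ifelse(sDen > 0, sNum / sDen, NA_real_) -
      ifelse(dDen > 0, dNum / dDen, NA_real_)
  }
  attr(out, "centers") <- attr(sim, "centers")
  out
}

#' Write a metric series as tidy TSV
#'
#' Long-format export (participant, roi, condition, time, value) of
#' per-participant metric matrices or vectors.
#'
#' @param metricList list over participants of trials x centers matrices
#'   (attribute \code{centers}) or per-center vectors.
#' @param path output file.
#' @param roi ROI label written to every row.
#' @param condition optional per-participant condition label vector.
#' @return the path, invisibly.
#' @export
writeMetricTSV <- function(metricList, path, roi = NA_character_,
                           condition = NULL) {
  rows <- do.call(rbind, lapply(seq_along(metricList), function(i) {
    m <- metricList[[i]]
    centers <- attr(m, "centers")
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (is.null(centers)) centers <- seq_len(ncol(m))
    data.frame(participant = i, roi = roi,
               condition = if (is.null(condition)) NA_character_ else
                 condition[[i]],
               trial = rep(seq_len(nrow(m)), times = ncol(m)),
               time = rep(centers, each = nrow(m)),
               value = as.numeric(m))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
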