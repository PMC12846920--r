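# Cross-ROI coordination: trial-level correlation of representational
# metrics between regions across all time-point combinations (temporal
# generalization maps), and theta-power-to-representation correlations.

# Optionally z-score a trials x centers metric within condition labels.
.zWithin <- function(x, labels) {
  for (lv in unique(labels)) {
    i <- labels == lv
    mu <- colMeans(x[i, , drop = FALSE])
    sd <- apply(x[i, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    x[i, ] <- sweep(sweep(x[i, , drop = FALSE], 2, mu), 2, sd, "/")
  }
  x
}

.alignTrials <- function(a, b) {
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
  } else {
    if (nrow(a) != nrow(b))
      stop("metric matrices differ in trial count and carry no trial ids")
    list(a = a, b = b)
  }
}

#' Cross-ROI trial-level coordination map
#'
#' Correlates two per-trial metric time courses (e.g. single-trial item
#' stability in two ROIs) across trials at every combination of time
#' points, yielding a temporal generalization map per participant. Group
#' inference is a one-sample t test of the Fisher-z rho values against zero
#' per time-by-time bin, corrected by 2D cluster-based permutation in which
#' the trial order of the second ROI is shuffled within participant.
#'
#' @param metricAList,metricBList lists over participants of trials x
#'   centers matrices (rownames = trial ids for alignment after
#'   ROI-dependent rejection; the intersection of retained trials is used).
#' @param centersA,centersB window-center times (taken from the matrices'
#'   \code{"centers"} attribute when absent).
#' @param labelsList optional per-participant condition labels (aligned
#'   with rownames) for within-condition z-scoring.
#' @param zWithinCondition z-score metrics within condition first
#'   (control against condition-mean-driven correlations).
#' @param nPerm,clusterAlpha,seed permutation settings.
#' @param minTrials minimum common trials (default 8); participants below
#'   are excluded.
#' @return list with \code{rhoMaps} (per participant), \code{tmap},
#'   \code{test} (\linkS4class{ClusterTestResult}), \code{centersA},
#'   \code{centersB}, \code{nIncluded}.
#' @export
crossRoiTrialCorrelation <- function(metricAList, metricBList,
                                     centersA = NULL, centersB = NULL,
                                     labelsList = NULL,
                                     zWithinCondition = FALSE,
                                     nPerm = 1000, clusterAlpha = 0.05,
                                     seed = 1, minTrials = 8) {
  nP <- length(metricAList)
  if (is.null(centersA)) centersA <- attr(metricAList[[1]], "centers")
  if (is.null(centersB)) centersB <- attr(metricBList[[1]], "centers")
  set.seed(seed)
  keep <- logical(nP)
  rhoMaps <- list()
  zMaps <- list()
  permAcc1 <- 0; permAcc2 <- 0
  nA <- ncol(metricAList[[1]]); nB <- ncol(metricBList[[1]])
  for (i in seq_len(nP)) {
    al <- .alignTrials(metricAList[[i]], metricBList[[i]])
    a <- al$a; b <- al$b
    if (nrow(a) < minTrials) next
    keep[i] <- TRUE
    if (zWithinCondition) {
      if (is.null(labelsList))
        stop("labelsList required for within-condition z-scoring")
      lab <- labelsList[[i]][rownames(a)]
      a <- .zWithin(a, lab)
      b <- .zWithin(b, lab)
    }
    ra <- .rankScale(a)
    rb <- .rankScale(b)
    rho <- crossprod(ra, rb)
    rhoMaps[[i]] <- rho
    zMaps[[i]] <- fisherZ(rho)
    nT <- nrow(a)
    zp <- matrix(0, nPerm, nA * nB)
    for (p in seq_len(nPerm)) {
      zp[p, ] <- as.numeric(fisherZ(crossprod(ra[sample.int(nT), ,
                                                 drop = FALSE], rb)))
    }
    permAcc1 <- permAcc1 + zp
    permAcc2 <- permAcc2 + zp^2
  }
  nIncl <- sum(keep)
  if (nIncl < 2) stop("fewer than 2 includable participants")
  zArr <- do.call(rbind, lapply(zMaps[keep], as.numeric))
  zArr[!is.finite(zArr)] <- 0
  tObs <- .oneSampleT(zArr)
  mP <- permAcc1 / nIncl
  vP <- pmax(permAcc2 / nIncl - mP^2, 0) * nIncl / (nIncl - 1)
  tPerm <- mP / sqrt(vP / nIncl)
  tPerm[!is.finite(tPerm)] <- 0
  thr <- stats::qt(1 - clusterAlpha / 2, df = nIncl - 1)
  nullMax <- .permMaxClusterMassC(as.numeric(tPerm), c(nPerm, nA, nB), thr)
  test <- .makeClusterResult(matrix(tObs, nA, nB), nullMax, thr, nPerm,
                             clusterAlpha,
                             scheme = "within-participant-trial-shuffle",
                             seed = seed, rowValues = centersA,
                             colValues = centersB)
  list(rhoMaps = rhoMaps[keep], tmap = test@statMap, test = test,
       centersA = centersA, centersB = centersB, nIncluded = nIncl)
}

#' Correlation of single-trial theta power with representational metrics
#'
#' Correlates per-trial theta-cluster power scalars (z-scored within
#' condition to remove condition-mean differences) with a per-trial
#' representational metric across trials, per participant; group inference
#' is a two-sided t test of the Fisher-z rho values against zero. In
#' window-averaged mode the metric is first averaged over the theta-cluster
#' time window; in time-resolved mode a rho time course is built and
#' corrected by 1D cluster permutation (theta scalars shuffled across
#' trials).
#'
#' @param thetaList list over participants of per-trial theta scalars
#'   (named by trial id when alignment is needed).
#' @param metricList list over participants of trials x centers metric
#'   matrices.
#' @param mode \code{"window"} or \code{"time-resolved"}.
#' @param window window-center range (s) for window-averaged mode.
#' @param centers window-center times (default from attribute).
#' @param nPerm,clusterAlpha,seed permutation settings (time-resolved).
#' @param minTrials minimum trials (default 8).
#' @return window mode: list with \code{rho} (per participant), \code{t},
#'   \code{df}, \code{p}, \code{nIncluded}. Time-resolved mode: list with
#'   \code{rhoCourse} (participants x centers), \code{test}, \code{centers},
#'   \code{nIncluded}.
#' @export
thetaMetricCorrelation <- function(thetaList, metricList,
                                   mode = c("window", "time-resolved"),
                                   window = NULL, centers = NULL,
                                   nPerm = 1000, clusterAlpha = 0.05,
                                   seed = 1, minTrials = 8) {
  mode <- match.arg(mode)
  if (is.null(centers)) centers <- attr(metricList[[1]], "centers")
  nP <- length(thetaList)
  set.seed(seed)
  if (mode == "window") {
    if (is.null(window)) stop("window required in window-averaged mode")
    rho <- rep(NA_real_, nP)
    for (i in seq_len(nP)) {
      th <- thetaList[[i]]
      met <- metricList[[i]]
      if (length(th) < minTrials) next
      cols <- centers >= window[1] & centers <= window[2]
      mv <- rowMeans(met[, cols, drop = FALSE])
      rho[i] <- suppressWarnings(stats::cor(th, mv, method = "spearman"))
    }
    ok <- is.finite(rho)
    if (sum(ok) < 2) stop("fewer than 2 includable participants")
    tt <- .safeTTest(fisherZ(rho[ok]))
    list(rho = rho, t = tt$t, df = tt$df, p = tt$p, nIncluded = sum(ok))
  } else {
    keep <- logical(nP)
    courses <- list()
    acc1 <- 0; acc2 <- 0
    nC <- length(centers)
    for (i in seq_len(nP)) {
      th <- thetaList[[i]]
      met <- metricList[[i]]
      if (length(th) < minTrials) next
      keep[i] <- TRUE
      rt <- .rankScale(matrix(th, ncol = 1))
      rm <- .rankScale(met)
      courses[[i]] <- fisherZ(as.numeric(crossprod(rt, rm)))
      nT <- length(th)
      zp <- matrix(0, nPerm, nC)
      for (p in seq_len(nPerm)) {
        zp[p, ] <- fisherZ(as.numeric(crossprod(rt[sample.int(nT), ,
                                                   drop = FALSE], rm)))
      }
      acc1 <- acc1 + zp
      acc2 <- acc2 + zp^2
    }
    nIncl <- sum(keep)
    if (nIncl < 2) stop("fewer than 2 includable participants")
    mat <- do.call(rbind, courses[keep])
    mat[!is.finite(mat)] <- 0
    tObs <- .oneSampleT(mat)
    mP <- acc1 / nIncl
    vP <- pmax(acc2 / nIncl - mP^2, 0) * nIncl / (nIncl - 1)
    tPerm <- mP / sqrt(vP / nIncl)
    tPerm[!is.finite(tPerm)] <- 0
    thr <- stats::qt(1 - clusterAlpha / 2, df = nIncl - 1)
    nullMax <- .permMaxClusterMassC(as.numeric(tPerm), c(nPerm, 1L, nC),
                                    thr)
    test <- .makeClusterResult(matrix(tObs, 1, nC), nullMax, thr, nPerm,
                               clusterAlpha,
                               scheme = "within-participant-trial-shuffle",
                               seed = seed, rowValues = 1,
                               colValues = centers)
    list(rhoCourse = mat, test = test, centers = centers,
         nIncluded = nIncl)
  }
}
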