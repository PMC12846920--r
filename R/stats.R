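# Inference machinery: cluster-based permutation tests (1D / 2D maps),
# trial-position Wilcoxon learning curves, and repeated-measures ANOVA.

# Build a ClusterTestResult from an observed statistic map and a permutation
# null of maximum |cluster mass| values. Shared by all cluster tests.
.makeClusterResult <- function(statMap, nullMax, threshold, nPerm,
                               clusterAlpha, scheme, seed,
                               rowValues = numeric(), colValues = numeric()) {
  statMap <- as.matrix(statMap)
  lab <- .labelClustersC(statMap, threshold)
  masses <- lab$masses
  if (length(masses)) {
    p <- vapply(abs(masses), function(m) {
      (1 + sum(nullMax >= m)) / (1 + nPerm)
    }, numeric(1))
    cl <- data.frame(
      cluster = seq_along(masses),
      sign = ifelse(masses >= 0, "positive", "negative"),
      mass = masses,
      nBins = as.integer(tabulate(lab$labels[lab$labels > 0],
                                  nbins = length(masses))),
      p = p
    )
    if (length(rowValues) == nrow(statMap) &&
        length(colValues) == ncol(statMap)) {
      ext <- lapply(seq_along(masses), function(k) {
        idx <- which(lab$labels == k, arr.ind = TRUE)
        c(rowMin = min(rowValues[idx[, 1]]), rowMax = max(rowValues[idx[, 1]]),
          colMin = min(colValues[idx[, 2]]), colMax = max(colValues[idx[, 2]]))
      })
      ext <- do.call(rbind, ext)
      cl <- cbind(cl, as.data.frame(ext))
    }
  } else {
    cl <- data.frame(cluster = integer(), sign = character(),
                     mass = numeric(), nBins = integer(), p = numeric())
  }
  new("ClusterTestResult",
      statMap = statMap, clusters = cl, labels = lab$labels,
      nullMax = nullMax, nPerm = nPerm, clusterAlpha = clusterAlpha,
      threshold = threshold, scheme = scheme, seed = as.numeric(seed),
      rowValues = as.numeric(rowValues), colValues = as.numeric(colValues))
}

# Random subset indicator matrix: nPerm x n with exactly k ones per row.
.permIndicator <- function(nPerm, n, k) {
  m <- matrix(0, nPerm, n)
  for (p in seq_len(nPerm)) m[p, sample.int(n, k)] <- 1
  m
}

#' Cluster-based permutation test for paired condition maps
#'
#' Group-level paired comparison of two conditions measured per trial within
#' each participant, corrected for multiple comparisons over a 1D or 2D bin
#' grid by cluster-based permutation. Per permutation, condition labels are
#' shuffled across trials within each participant independently, participant
#' condition means are recomputed, the group paired t map is rebuilt, and the
#' maximum |summed t| over (sign-homogeneous, 4-connected) supra-threshold
#' clusters is stored. Observed clusters are ranked against this null with
#' the p convention (1 + #\{null >= observed\}) / (1 + nPerm).
#'
#' An alternative participant-level sign-flip scheme
#' (\code{scheme = "signflip"}) flips the sign of each participant's
#' condition-difference map instead; it is provided for sensitivity checks
#' and for one-sample (difference vs zero) designs where trial labels are
#' not exchangeable.
#'
#' @param data list over participants; each element a trials x bins numeric
#'   matrix (bins = prod of the map dimensions, column-major).
#' @param labels list over participants of 2-level condition labels (one per
#'   trial). The contrast is level1 minus level2 of
#'   \code{factor(labels[[i]])}. Ignored for \code{scheme = "signflip"},
#'   where \code{data} must already hold one row set of per-trial difference
#'   values or per-participant maps (one row per participant element).
#' @param mapDim integer vector of map dimensions (length 1 or 2).
#' @param nPerm number of permutations (default 1000; < 100 warns).
#' @param clusterAlpha cluster-forming alpha (two-tailed, default 0.05).
#' @param seed RNG seed; recorded in the result.
#' @param scheme \code{"trial"} (default) or \code{"signflip"}.
#' @param rowValues,colValues optional axis values for cluster extents.
#' @return a \linkS4class{ClusterTestResult}.
#' @export
clusterPermutation <- function(data, labels = NULL, mapDim,
                               nPerm = 1000, clusterAlpha = 0.05, seed = 1,
                               scheme = c("trial", "signflip"),
                               rowValues = numeric(), colValues = numeric()) {
  scheme <- match.arg(scheme)
  if (length(data) < 2) stop("need at least 2 participants")
  if (nPerm < 100) warning("fewer than 100 permutations")
  nBins <- ncol(data[[1]])
  if (prod(mapDim) != nBins) stop("mapDim inconsistent with data columns")
  nP <- length(data)
  set.seed(seed)

  if (scheme == "trial") {
    if (is.null(labels) || length(labels) != nP)
      stop("labels must be a list parallel to data")
    diffs <- matrix(NA_real_, nP, nBins)
    s1 <- matrix(0, nPerm, nBins)
    s2 <- matrix(0, nPerm, nBins)
    for (i in seq_len(nP)) {
      f <- if (is.factor(labels[[i]])) droplevels(labels[[i]]) else
        factor(labels[[i]])
      if (nlevels(f) != 2) stop("participant ", i, " lacks both conditions")
      x <- data[[i]]
      i1 <- f == levels(f)[1]
      n1 <- sum(i1); n2 <- sum(!i1)
      diffs[i, ] <- colMeans(x[i1, , drop = FALSE]) -
        colMeans(x[!i1, , drop = FALSE])
      m1 <- .permIndicator(nPerm, nrow(x), n1)
      d <- (m1 %*% x) / n1 - ((1 - m1) %*% x) / n2
      s1 <- s1 + d
      s2 <- s2 + d^2
    }
  } else {
    diffs <- do.call(rbind, lapply(data, function(x) {
      if (is.matrix(x) && nrow(x) > 1) colMeans(x) else as.numeric(x)
    }))
    signs <- matrix(sample(c(-1, 1), nPerm * nP, replace = TRUE), nPerm, nP)
    s1 <- signs %*% diffs
    s2 <- matrix(colSums(diffs^2), nPerm, nBins, byrow = TRUE)
  }

  tObs <- .oneSampleT(diffs)
  mPerm <- s1 / nP
  vPerm <- pmax(s2 / nP - mPerm^2, 0) * nP / (nP - 1)
  tPerm <- mPerm / sqrt(vPerm / nP)
  tPerm[!is.finite(tPerm)] <- 0
  thr <- stats::qt(1 - clusterAlpha / 2, df = nP - 1)
  nr <- mapDim[1]
  nc <- if (length(mapDim) > 1) mapDim[2] else 1L
  nullMax <- .permMaxClusterMassC(as.numeric(tPerm),
                                  c(nPerm, nr, nc), thr)
  nonfin <- !is.finite(tObs)
  if (any(nonfin)) tObs[nonfin] <- NA_real_
  .makeClusterResult(matrix(tObs, nr, nc), nullMax, thr, nPerm, clusterAlpha,
                     scheme = paste0("within-participant-", scheme,
                                     "-shuffle"),
                     seed = seed, rowValues = rowValues,
                     colValues = colValues)
}

# Wilcoxon signed-rank z statistic with zero-dropping and tie correction.
# Returns NA for fewer than 2 non-zero pairs.
.signedRankZ <- function(d) {
  allZero <- all(is.na(d) | d == 0)
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (allZero) return(0)   # identical pairs: no evidence either way
  if (n < 2) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  (w - mu) / sqrt(sig2)
}

#' Paired Wilcoxon signed-rank test
#'
#' Thin wrapper over \code{stats::wilcox.test} for paired samples, exposing
#' the zero-handling and exactness conventions used throughout the package
#' (zeros dropped; exact p for n <= 25 without ties, normal approximation
#' otherwise).
#'
#' @param x,y paired numeric vectors (NAs dropped pairwise).
#' @return list with \code{statistic} (V), \code{p.value}, \code{n} (pairs
#'   used) and \code{z} (normal-approximation z).
#' @export
signedRankTest <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  res <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       n = length(x), z = .signedRankZ(x - y))
}

#' Trial-position learning-curve comparison
#'
#' Compares the ratings of two cue roles at every within-condition ordinal
#' position (1st vs 1st, 2nd vs 2nd, ...) with paired Wilcoxon signed-rank
#' tests across participants, then corrects over positions with a 1D
#' cluster-based permutation built by randomly swapping the two conditions'
#' ratings at every trial within each participant (equivalently, flipping the
#' sign of each paired difference).
#'
#' @param ratings data.frame with columns \code{participant}, \code{phase},
#'   \code{role}, \code{ordinal}, \code{rating} (NA = missing response).
#' @param phase experimental phase to analyse.
#' @param pair character vector of the two roles compared (level1 - level2).
#' @param nPerm permutations (default 1000).
#' @param clusterAlpha cluster-forming alpha (default 0.05).
#' @param minPairs positions with fewer valid pairs are skipped (default 5).
#' @param seed RNG seed.
#' @param scheme \code{"participant"} (labels shuffled per participant,
#'   default) or \code{"global"} (the same swap pattern applied to all
#'   participants).
#' @return list with \code{z} and \code{p} per position, \code{nPairs},
#'   \code{test} (a \linkS4class{ClusterTestResult}) and \code{onsets}
#'   (first position of each cluster significant at p <= 0.05).
#' @export
learningCurveTest <- function(ratings, phase, pair, nPerm = 1000,
                              clusterAlpha = 0.05, minPairs = 5, seed = 1,
                              scheme = c("participant", "global")) {
  scheme <- match.arg(scheme)
  sub <- ratings[ratings$phase == phase & ratings$role %in% pair, ]
  wide <- function(role) {
    s <- sub[sub$role == role, ]
    tapply(s$rating, list(s$participant, s$ordinal), mean)
  }
  a <- wide(pair[1]); b <- wide(pair[2])
  common <- intersect(rownames(a), rownames(b))
  pos <- intersect(colnames(a), colnames(b))
  d <- a[common, pos, drop = FALSE] - b[common, pos, drop = FALSE]
  nPos <- ncol(d)
  set.seed(seed)
  zObs <- apply(d, 2, .signedRankZ)
  nPairs <- colSums(!is.na(d) & d != 0)
  skip <- colSums(!is.na(d)) < minPairs
  zObs[skip] <- NA_real_
  pObs <- 2 * stats::pnorm(-abs(zObs))

  # permutation null: sign flips of the paired differences
  zPerm <- matrix(NA_real_, nPerm, nPos)
  for (j in seq_len(nPos)) {
    if (skip[j]) next
    dj <- d[, j]
    dj <- dj[!is.na(dj) & dj != 0]
    n <- length(dj)
    if (n < 2) next
    r <- rank(abs(dj))
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    if (scheme == "participant") {
      flips <- matrix(sample(c(TRUE, FALSE), nPerm * n, replace = TRUE),
                      nPerm, n)
    } else {
      f <- sample(c(TRUE, FALSE), nPerm, replace = TRUE)
      flips <- matrix(f, nPerm, n)
    }
    pos_d <- dj > 0
    wp <- (1 - flips) %*% (r * pos_d) + flips %*% (r * !pos_d)
    zPerm[, j] <- (wp - mu) / sig
  }
  zPerm[is.na(zPerm)] <- 0
  thr <- stats::qnorm(1 - clusterAlpha / 2)
  nullMax <- .permMaxClusterMassC(as.numeric(zPerm), c(nPerm, 1L, nPos), thr)
  res <- .makeClusterResult(matrix(zObs, 1, nPos), nullMax, thr, nPerm,
                            clusterAlpha,
                            scheme = paste0("condition-swap-", scheme),
                            seed = seed,
                            rowValues = 1, colValues = as.numeric(pos))
  sig <- clusters(res)
  onsets <- if (nrow(sig)) sig$colMin[sig$p <= 0.05] else numeric()
  list(z = zObs, p = pObs, nPairs = nPairs, positions = as.numeric(pos),
       test = res, onsets = onsets)
}

#' Two-way repeated-measures ANOVA on ratings
#'
#' Standard two-way within-participant decomposition (cue type x phase) with
#' partial eta squared effect sizes and Bonferroni-corrected paired t post
#' hoc tests across cue types. Participants with incomplete cells are
#' dropped listwise.
#'
#' @param data data.frame with columns \code{participant}, \code{cue},
#'   \code{phase} and the response in \code{dv}; multiple rows per cell are
#'   averaged.
#' @param dv name of the response column (default \code{"rating"}).
#' @return list with \code{effects} (data.frame: effect, df1, df2, F, p,
#'   petaSq), \code{posthoc} (pairwise cue comparisons, Bonferroni), and
#'   \code{n} (participants analysed).
#' @export
rmAnova2way <- function(data, dv = "rating") {
  cells <- stats::aggregate(data[[dv]],
                            by = list(participant = data$participant,
                                      cue = data$cue, phase = data$phase),
                            FUN = mean, na.rm = TRUE)
  names(cells)[4] <- "y"
  cells <- cells[is.finite(cells$y), ]
  nCells <- length(unique(cells$cue)) * length(unique(cells$phase))
  cnt <- table(cells$participant)
  keep <- names(cnt)[cnt == nCells]
  cells <- cells[cells$participant %in% keep, ]
  n <- length(keep)
  if (n < 3) stop("fewer than 3 participants with complete cells")
  cells$participant <- factor(cells$participant)
  cells$cue <- factor(cells$cue)
  cells$phase <- factor(cells$phase)

  fit <- stats::aov(y ~ cue * phase + Error(participant / (cue * phase)),
                    data = cells)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    err <- trimws(rownames(tab)) == "Residuals"
    ssEff <- tab[row, "Sum Sq"]; ssErr <- tab[err, "Sum Sq"]
    f <- tab[row, "F value"]; p <- tab[row, "Pr(>F)"]
    if (ssEff < 1e-12) { f <- 0; p <- 1 }
    peta <- if (ssEff + ssErr < 1e-12) 0 else ssEff / (ssEff + ssErr)
    data.frame(effect = term, df1 = tab[row, "Df"], df2 = tab[err, "Df"],
               F = f, p = p, petaSq = peta)
  }
  effects <- rbind(pull("Error: participant:cue", "cue"),
                   pull("Error: participant:phase", "phase"),
                   pull("Error: participant:cue:phase", "cue:phase"))
  rownames(effects) <- NULL

  cues <- levels(cells$cue)
  cueMeans <- tapply(cells$y, list(cells$participant, cells$cue), mean)
  pairsIdx <- utils::combn(length(cues), 2)
  k <- ncol(pairsIdx)
  posthoc <- do.call(rbind, lapply(seq_len(k), function(j) {
    i1 <- pairsIdx[1, j]; i2 <- pairsIdx[2, j]
    tt <- stats::t.test(cueMeans[, i1], cueMeans[, i2], paired = TRUE)
    data.frame(contrast = paste(cues[i1], "vs", cues[i2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, pBonf = min(1, tt$p.value * k))
  }))
  list(effects = effects, posthoc = posthoc, n = n)
}
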