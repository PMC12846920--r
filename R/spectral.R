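# Variable-cycle Morlet time-frequency decomposition, power normalization,
# and condition contrasts on time-frequency maps.

#' Variable-cycle frequency grid
#'
#' The 44-frequency analysis grid: 29 linear steps from 1 to 29 Hz with
#' cycles increasing linearly from 3 to 6, and 15 linear steps from 30 to
#' 100 Hz with cycles from 6 to 12.
#'
#' @return list with \code{freqs} (Hz) and \code{cycles}.
#' @examples
#' g <- buildFrequencyGrid()
#' length(g$freqs)  # 44
#' @export
buildFrequencyGrid <- function() {
  low <- seq(1, 29, length.out = 29)
  high <- seq(30, 100, length.out = 15)
  list(freqs = c(low, high),
       cycles = c(seq(3, 6, length.out = 29), seq(6, 12, length.out = 15)))
}

# Cache of sparse wavelet projection operators (key -> list(re, im, cols)).
.wavCache <- new.env(parent = emptyenv())

# Build (or fetch) the sparse operator that evaluates the complex Morlet
# convolution of an epoch at the requested output instants. Columns are
# ordered frequency-major: (f1 t1, f1 t2, ..., f2 t1, ...).
.waveletOperator <- function(times, fs, freqs, cycles, toi, edge) {
  key <- paste(length(times), round(times[1] * fs), fs, edge,
               paste(signif(freqs, 8), collapse = ","),
               paste(signif(cycles, 8), collapse = ","),
               paste(round(toi * fs), collapse = ","), sep = "|")
  hit <- .wavCache[[key]]
  if (!is.null(hit)) return(hit)
  nT <- length(times)
  t0 <- times[1]
  centerIdx <- round((toi - t0) * fs) + 1L
  iL <- list(); jL <- list(); reL <- list(); imL <- list()
  naCols <- integer()
  col <- 0L
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]; cyc <- cycles[fi]
    h <- round(cyc / (2 * f) * fs)
    sigma <- cyc / (2 * pi * f)
    supp <- (-h):h
    tt <- supp / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
    for (ci in seq_along(centerIdx)) {
      col <- col + 1L
      idx <- centerIdx[ci] + supp
      inb <- idx >= 1L & idx <= nT
      if (!all(inb)) {
        if (edge == "strict")
          stop(sprintf(
            "output time %.3f s at %.2f Hz intersects the epoch edge",
            toi[ci], f))
        if (edge == "na") {
          naCols <- c(naCols, col)
          next
        }
        idx <- idx[inb]
        wk <- w[inb]
      } else wk <- w
      wk <- wk / sqrt(sum(Mod(wk)^2))
      iL[[col]] <- idx
      jL[[col]] <- rep.int(col, length(idx))
      reL[[col]] <- Re(wk)
      imL[[col]] <- Im(wk)
    }
  }
  nCol <- length(freqs) * length(toi)
  i <- unlist(iL); j <- unlist(jL)
  op <- list(
    re = Matrix::sparseMatrix(i = i, j = j, x = unlist(reL),
                              dims = c(nT, nCol)),
    im = Matrix::sparseMatrix(i = i, j = j, x = unlist(imL),
                              dims = c(nT, nCol)),
    naCols = naCols)
  .wavCache[[key]] <- op
  op
}

#' Morlet wavelet time-frequency decomposition
#'
#' Decomposes epoched data with complex Morlet wavelets of variable cycle
#' number (Gaussian SD \code{cycles / (2 pi f)}, support
#' \code{+/- cycles / (2 f)}); power is the squared magnitude of the
#' wavelet coefficient, evaluated at the requested output instants.
#' Output instants whose wavelet support extends beyond the epoch are edge
#' cases: with \code{edge = "strict"} (default) the call errors, with
#' \code{"truncate"} the wavelet is clipped to the epoch and renormalized
#' (slight bias at the lowest frequencies), with \code{"na"} the bin is NA.
#'
#' @param epochs an \linkS4class{EpochArray}.
#' @param grid frequency grid from \code{\link{buildFrequencyGrid}}.
#' @param window output time range in seconds (cue-locked), default the cue
#'   presentation period c(0, 1.75).
#' @param timeStep output step in seconds (default 0.02).
#' @param freqRange optional c(lo, hi) restriction of the grid in Hz.
#' @param edge edge handling: \code{"strict"}, \code{"truncate"} or
#'   \code{"na"}.
#' @return a \linkS4class{TFRArray} (normalization \code{"raw"}).
#' @export
morletTFR <- function(epochs, grid = buildFrequencyGrid(),
                      window = c(0, 1.75), timeStep = 0.02,
                      freqRange = NULL, edge = c("strict", "truncate",
                                                 "na")) {
  edge <- match.arg(edge)
  fs <- epochs@samplingRate
  keep <- if (is.null(freqRange)) seq_along(grid$freqs) else
    which(grid$freqs >= freqRange[1] & grid$freqs <= freqRange[2])
  freqs <- grid$freqs[keep]; cycles <- grid$cycles[keep]
  toi <- seq(window[1], window[2], by = timeStep)
  op <- .waveletOperator(epochs@times, fs, freqs, cycles, toi, edge)
  d <- dim(epochs@data)
  x <- matrix(aperm(epochs@data, c(3, 1, 2)), nrow = d[3])
  # x: time x (trials*channels); project
  pre <- Matrix::crossprod(op$re, x)
  pim <- Matrix::crossprod(op$im, x)
  pw <- as.matrix(pre)^2 + as.matrix(pim)^2
  if (length(op$naCols)) pw[op$naCols, ] <- NA_real_
  # pw: (freq-major cols as rows: nToi fastest? cols ordered f-major with
  # toi fastest) x (trials*channels)
  power <- array(pw, c(length(toi), length(freqs), d[1], d[2]))
  power <- aperm(power, c(3, 4, 2, 1))
  new("TFRArray", power = power, freqs = freqs, cycles = cycles,
      times = toi, normalization = "raw", reference = "",
      channelInfo = epochs@channelInfo, trialInfo = epochs@trialInfo)
}

#' z-score wavelet power against a reference set
#'
#' Per channel x frequency, subtracts the reference mean and divides by the
#' reference SD, the reference statistics being pooled over all trials and
#' time points of the reference tensor(s) (normally all trials of the
#' experiment across phases). Set \code{perTime = TRUE} to normalize each
#' time point separately instead (sensitivity variant).
#'
#' @param tft a raw \linkS4class{TFRArray}.
#' @param reference a \linkS4class{TFRArray} or list of them supplying the
#'   reference trials; defaults to \code{tft} itself.
#' @param perTime logical; reference statistics per time point rather than
#'   pooled over time.
#' @return a z-scored \linkS4class{TFRArray}.
#' @export
zscorePower <- function(tft, reference = NULL, perTime = FALSE) {
  if (is.null(reference)) reference <- list(tft)
  if (is(reference, "TFRArray")) reference <- list(reference)
  nCh <- dim(tft@power)[2]; nF <- dim(tft@power)[3]
  nT <- dim(tft@power)[4]
  refMat <- do.call(rbind, lapply(reference, function(r) {
    stopifnot(dim(r@power)[2] == nCh, dim(r@power)[3] == nF)
    if (perTime) {
      matrix(r@power, nrow = dim(r@power)[1])
    } else {
      # collapse trials x times into rows: (trial, time) x (ch, freq)
      matrix(aperm(r@power, c(1, 4, 2, 3)),
             nrow = dim(r@power)[1] * dim(r@power)[4])
    }
  }))
  m <- colMeans(refMat)
  s <- apply(refMat, 2, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    if (perTime) {
      stop("zero reference SD in ", length(bad), " channel/frequency/time bins")
    }
    b <- arrayInd(bad[1], c(nCh, nF))
    stop(sprintf("zero reference SD for channel %s at %.1f Hz",
                 tft@channelInfo$channel[b[1]], tft@freqs[b[2]]))
  }
  if (perTime) {
    dimM <- c(nCh, nF, nT)
    mArr <- array(m, dimM); sArr <- array(s, dimM)
    nTr <- dim(tft@power)[1]
    z <- (tft@power - aperm(array(rep(mArr, nTr), c(dimM, nTr)),
                            c(4, 1, 2, 3))) /
      aperm(array(rep(sArr, nTr), c(dimM, nTr)), c(4, 1, 2, 3))
  } else {
    mArr <- array(m, c(nCh, nF))
    sArr <- array(s, c(nCh, nF))
    nTr <- dim(tft@power)[1]
    mFull <- aperm(array(rep(mArr, nTr * nT), c(nCh, nF, nTr, nT)),
                   c(3, 1, 2, 4))
    sFull <- aperm(array(rep(sArr, nTr * nT), c(nCh, nF, nTr, nT)),
                   c(3, 1, 2, 4))
    z <- (tft@power - mFull) / sFull
  }
  tft@power <- z
  tft@normalization <- "zscored"
  tft@reference <- sprintf("%d reference trials, %s",
                           sum(vapply(reference,
                                      function(r) dim(r@power)[1],
                                      numeric(1))),
                           if (perTime) "per-time" else
                             "pooled over trials and time")
  tft
}

#' Group-level time-frequency condition contrast
#'
#' Paired CS+ vs CS- contrast of z-scored power maps: per participant,
#' power is averaged over the ROI channels and over trials within each
#' condition; the group paired t statistic per time-frequency bin is then
#' corrected with a 2D cluster-based permutation (trial-label shuffling
#' within participant). Participants with fewer than \code{minTrials}
#' trials in either condition are dropped.
#'
#' @param tfts list over participants of z-scored \linkS4class{TFRArray}s
#'   (identical grids).
#' @param labels list over participants of per-trial condition labels
#'   (2 levels; contrast is level1 - level2 of \code{factor}).
#' @param freqRange analysis band in Hz (default c(1, 12); use c(1, 100)
#'   for the full-spectrum variant).
#' @param window analysis time range in seconds (default c(0, 1.75)).
#' @param nPerm,clusterAlpha,seed permutation settings.
#' @param minTrials minimum trials per condition per participant (8).
#' @param conditionLevels explicit condition order; the contrast (and the t
#'   map sign) is first minus second (default CS+ minus CS-, so the
#'   safety-related theta increase appears as a negative cluster).
#' @return list with \code{tmap} (freq x time), \code{freqs}, \code{times},
#'   \code{test} (a \linkS4class{ClusterTestResult}) and \code{nIncluded}.
#' @export
tfConditionContrast <- function(tfts, labels, freqRange = c(1, 12),
                                window = c(0, 1.75), nPerm = 1000,
                                clusterAlpha = 0.05, seed = 1,
                                minTrials = 8,
                                conditionLevels = c("CS+", "CS-")) {
  labels <- lapply(labels, factor, levels = conditionLevels)
  fsel <- which(tfts[[1]]@freqs >= freqRange[1] &
                  tfts[[1]]@freqs <= freqRange[2])
  tsel <- which(tfts[[1]]@times >= window[1] &
                  tfts[[1]]@times <= window[2])
  keep <- vapply(labels, function(l) {
    tb <- table(l)
    length(tb) == 2 && all(tb >= minTrials)
  }, logical(1))
  if (any(!keep))
    warning(sum(!keep), " participant(s) dropped (fewer than ", minTrials,
            " trials in a condition)")
  if (sum(keep) < 2) stop("fewer than 2 includable participants")
  data <- lapply(tfts[keep], function(tf) {
    p <- tf@power[, , fsel, tsel, drop = FALSE]
    roiAvg <- apply(p, c(1, 3, 4), mean)
    matrix(roiAvg, nrow = dim(p)[1])
  })
  res <- clusterPermutation(data, labels[keep],
                            mapDim = c(length(fsel), length(tsel)),
                            nPerm = nPerm, clusterAlpha = clusterAlpha,
                            seed = seed, scheme = "trial",
                            rowValues = tfts[[1]]@freqs[fsel],
                            colValues = tfts[[1]]@times[tsel])
  list(tmap = res@statMap, freqs = tfts[[1]]@freqs[fsel],
       times = tfts[[1]]@times[tsel], test = res, nIncluded = sum(keep))
}

#' Per-trial mean power within a time-frequency cluster
#'
#' Averages z-scored power over the channels and the bins of a given
#' time-frequency cluster, yielding one scalar per trial (the single-trial
#' theta metric). Optionally z-scores the scalars separately within each
#' condition to remove condition-mean differences before trial-level
#' correlation analyses.
#'
#' @param tft a z-scored \linkS4class{TFRArray}.
#' @param clusterBins logical matrix freqs x times selecting the cluster
#'   (must be non-empty), or a \linkS4class{ClusterTestResult} whose
#'   significant cluster bins are used.
#' @param labels optional per-trial condition labels; required when
#'   \code{zscoreWithinCondition}.
#' @param zscoreWithinCondition logical (default FALSE).
#' @return numeric vector of per-trial scalars, with attribute
#'   \code{"zscoredWithinCondition"}.
#' @export
clusterMeanPower <- function(tft, clusterBins, labels = NULL,
                             zscoreWithinCondition = FALSE) {
  if (is(clusterBins, "ClusterTestResult")) {
    sig <- clusters(clusterBins)
    ids <- sig$cluster[sig$p <= 0.05]
    clusterBins <- matrix(clusterBins@labels %in% ids,
                          nrow(clusterBins@labels))
  }
  if (!any(clusterBins)) stop("empty cluster")
  d <- dim(tft@power)
  stopifnot(nrow(clusterBins) == d[3], ncol(clusterBins) == d[4])
  binIdx <- which(clusterBins)
  pw <- matrix(aperm(tft@power, c(1, 2, 3, 4)), nrow = d[1] * d[2])
  # rows: (trial, channel); cols: (freq, time)
  sel <- pw[, binIdx, drop = FALSE]
  perTrialCh <- rowMeans(sel)
  scal <- rowMeans(matrix(perTrialCh, d[1], d[2]))
  if (zscoreWithinCondition) {
    if (is.null(labels)) stop("labels required for within-condition z-score")
    for (lv in unique(labels)) {
      i <- labels == lv
      scal[i] <- (scal[i] - mean(scal[i])) / stats::sd(scal[i])
    }
  }
  attr(scal, "zscoredWithinCondition") <- zscoreWithinCondition
  scal
}

#' Group test of condition-mean cluster power against baseline
#'
#' Averages the per-trial cluster-mean scalars within each condition per
#' participant and tests each condition's group mean against zero
#' (two-sided t). Because power is z-scored against the mean across all
#' trials of the experiment, zero is the all-trial baseline.
#'
#' @param scalarsList list over participants of per-trial scalars from
#'   \code{\link{clusterMeanPower}}.
#' @param labelsList list over participants of per-trial condition labels.
#' @return data.frame: condition, n, mean, t, df, p.
#' @export
conditionBaselineTest <- function(scalarsList, labelsList) {
  conds <- sort(unique(unlist(labelsList)))
  out <- do.call(rbind, lapply(conds, function(cond) {
    m <- vapply(seq_along(scalarsList), function(i) {
      sel <- labelsList[[i]] == cond
      if (!any(sel)) NA_real_ else mean(scalarsList[[i]][sel])
    }, numeric(1))
    tt <- .safeTTest(m[is.finite(m)])
    data.frame(condition = cond, n = tt$n, mean = mean(m, na.rm = TRUE),
               t = tt$t, df = tt$df, p = tt$p)
  }))
  rownames(out) <- NULL
  out
}
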