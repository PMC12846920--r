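# Preprocessing: zero-phase filtering, bipolar referencing, epileptiform
# artifact detection (amplitude / gradient / high-frequency z criteria) and
# cue-locked epoching with ROI-level trial rejection.

#' Zero-phase band and notch filtering
#'
#' High-pass (0.1 Hz), low-pass (200 Hz) and band-stop (49-51, 99-101,
#' 149-151 Hz) filtering, applied as the exact squared magnitude response of
#' 4th-order Butterworth filters in the frequency domain. This is zero-phase
#' by construction and matches a forward-backward IIR application in the
#' long-record limit while avoiding the numerical fragility of IIR
#' coefficients at very low normalized cutoffs.
#'
#' @param recording a \linkS4class{Recording} (sampling rate must exceed
#'   400 Hz).
#' @param highpass high-pass cutoff in Hz (default 0.1).
#' @param lowpass low-pass cutoff in Hz (default 200).
#' @param notch list of c(lo, hi) band-stop edges in Hz.
#' @param order Butterworth order per filter (default 4).
#' @return the filtered \linkS4class{Recording}.
#' @export
filterRecording <- function(recording, highpass = 0.1, lowpass = 200,
                            notch = list(c(49, 51), c(99, 101),
                                         c(149, 151)),
                            order = 4) {
  fs <- recording@samplingRate
  if (fs <= 400) stop("sampling rate must exceed 400 Hz")
  if (fs <= 2 * lowpass) stop("sampling rate must exceed twice the low-pass")
  h2fun <- function(f) {
    h <- .butterHighpassH2(f, highpass, order) *
      .butterLowpassH2(f, lowpass, order)
    for (b in notch) h <- h * .butterBandstopH2(f, b[1], b[2], order)
    h
  }
  key <- paste("bandnotch", highpass, lowpass, order,
               paste(unlist(notch), collapse = "-"))
  recording@data <- .fftFilterRows(recording@data, fs, h2fun, key = key)
  recording@processing <- c(recording@processing, "filter")
  recording
}

#' Bipolar re-referencing of depth-electrode contacts
#'
#' Subtracts adjacent contacts on the same electrode shaft
#' (contact_i - contact_{i+1}, ordered from the deepest contact), yielding
#' N-1 virtual channels per N-contact shaft. A virtual channel inherits the
#' ROI of its deeper contact; shafts with a single contact yield no output
#' and a warning.
#'
#' @param recording a \linkS4class{Recording} whose channelInfo carries
#'   shaft grouping and within-shaft contact order.
#' @return a \linkS4class{Recording} of virtual channels.
#' @export
bipolarReference <- function(recording) {
  ci <- recording@channelInfo
  outData <- list(); outInfo <- list()
  for (sh in unique(ci$shaft)) {
    rows <- which(ci$shaft == sh)
    rows <- rows[order(ci$contact[rows])]
    if (length(rows) < 2) {
      warning("shaft ", sh, " has a single contact; no virtual channel")
      next
    }
    for (k in seq_len(length(rows) - 1)) {
      i <- rows[k]; j <- rows[k + 1]
      outData[[length(outData) + 1]] <-
        recording@data[i, ] - recording@data[j, ]
      outInfo[[length(outInfo) + 1]] <- data.frame(
        channel = paste0(ci$channel[i], "-", ci$channel[j]),
        shaft = sh, contact = ci$contact[i], roi = ci$roi[i])
    }
  }
  if (!length(outData)) stop("no shaft with >= 2 contacts")
  recording@data <- do.call(rbind, outData)
  recording@channelInfo <- do.call(rbind, outInfo)
  recording@processing <- c(recording@processing, "bipolar")
  recording
}

# Dilate core indices by +/- pad samples (union of intervals), per channel.
.dilateMask <- function(core, n, pad) {
  idx <- which(core)
  if (!length(idx)) return(logical(n))
  lo <- pmax(idx - pad, 1L)
  hi <- pmin(idx + pad, n)
  delta <- integer(n + 1L)
  dl <- tabulate(lo, nbins = n)
  delta[seq_len(n)] <- dl
  dh <- tabulate(hi + 1L, nbins = n + 1L)
  delta <- delta - c(0L, dh[seq_len(n)])
  cumsum(delta[seq_len(n)]) > 0
}

#' Detect epileptiform-like artifacts
#'
#' Per channel, three whole-recording z-scored criteria are computed: (1)
#' amplitude, (2) gradient (difference of adjacent samples) and (3)
#' amplitude after a 250 Hz high-pass. A sample is flagged as an artifact
#' core if any criterion reaches |z| >= 6, or if the amplitude criterion
#' reaches |z| >= 4 together with a gradient or high-frequency |z| >= 3.
#' Flagged cores are padded by +/- 1000 ms.
#'
#' The detection is meant to run on the unfiltered (raw or bipolar) data:
#' the 250 Hz criterion targets spike energy that the 200 Hz low-pass of
#' \code{\link{filterRecording}} would remove.
#'
#' @param recording a \linkS4class{Recording}.
#' @param zAny single-criterion threshold (default 6).
#' @param zAmp,zAux conjunction thresholds (defaults 4 and 3).
#' @param padSeconds padding around cores in seconds (default 1).
#' @param hfCutoff high-pass cutoff of the third criterion in Hz (250).
#' @param hf optional precomputed high-passed data matrix (same shape as
#'   the recording data), e.g. from a fused filtering pass.
#' @return an \linkS4class{ArtifactMask}.
#' @export
detectArtifacts <- function(recording, zAny = 6, zAmp = 4, zAux = 3,
                            padSeconds = 1, hfCutoff = 250, hf = NULL) {
  fs <- recording@samplingRate
  x <- recording@data
  n <- ncol(x)
  pad <- round(padSeconds * fs)
  zs <- function(v, label, ch) {
    s <- stats::sd(v)
    if (s == 0 || !is.finite(s))
      stop("zero-variance ", label, " in channel ",
           recording@channelInfo$channel[ch], ": z-score undefined")
    (v - mean(v)) / s
  }
  if (is.null(hf))
    hf <- .fftFilterRows(x, fs,
                         function(f) .butterHighpassH2(f, hfCutoff, 4),
                         key = paste("hf", hfCutoff))
  mask <- matrix(FALSE, nrow(x), n)
  for (ch in seq_len(nrow(x))) {
    za <- abs(zs(x[ch, ], "amplitude", ch))
    grad <- c(diff(x[ch, ]), 0)
    zg <- abs(zs(grad, "gradient", ch))
    zh <- abs(zs(hf[ch, ], "high-frequency amplitude", ch))
    core <- za >= zAny | zg >= zAny | zh >= zAny |
      (za >= zAmp & (zg >= zAux | zh >= zAux))
    mask[ch, ] <- .dilateMask(core, n, pad)
  }
  new("ArtifactMask", mask = mask,
      thresholds = c(any = zAny, amplitude = zAmp, auxiliary = zAux),
      padSeconds = padSeconds, samplingRate = fs)
}

#' Cue-locked epoching with artifact-based trial rejection
#'
#' Segments the recording into epochs around each cue onset (default -3 to
#' 4 s) for the channels of the requested ROI set. An epoch is rejected if
#' any selected channel carries a flagged sample anywhere inside the epoch
#' window (ROI-level rejection, so every retained trial has a complete
#' spectral-spatial feature vector). Conditions retaining fewer than
#' \code{minTrials} trials mark the participant-ROI as excluded for the
#' corresponding contrasts.
#'
#' @param recording a (typically bipolar-referenced, filtered)
#'   \linkS4class{Recording}.
#' @param schedule the TrialSchedule of one phase.
#' @param mask optional \linkS4class{ArtifactMask} aligned with
#'   \code{recording}.
#' @param window epoch window in seconds relative to cue onset.
#' @param roi optional ROI name(s); default all channels.
#' @param minTrials minimum retained trials per condition (default 8).
#' @return an \linkS4class{EpochArray}.
#' @export
epochRecording <- function(recording, schedule, mask = NULL,
                           window = c(-3, 4), roi = NULL, minTrials = 8) {
  fs <- recording@samplingRate
  phase <- schedule$phase[1]
  ev <- recording@events
  cueEv <- ev[ev$marker == "cue" & ev$phase == phase, ]
  cueEv <- cueEv[order(cueEv$trial), ]
  if (nrow(cueEv) != nrow(schedule))
    stop("event count (", nrow(cueEv), ") disagrees with schedule (",
         nrow(schedule), ")")
  chSel <- if (is.null(roi)) seq_len(nrow(recording@channelInfo)) else
    which(recording@channelInfo$roi %in% roi)
  if (!length(chSel)) stop("no channels in ROI ", paste(roi, collapse = ","))

  off <- round(window * fs)
  tIdx <- off[1]:off[2]
  nT <- length(tIdx)
  n <- ncol(recording@data)

  keep <- logical(nrow(schedule))
  reasons <- character(nrow(schedule))
  segs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    s0 <- cueEv$sample[i]
    idx <- s0 + tIdx
    if (idx[1] < 1 || idx[nT] > n) {
      reasons[i] <- "epoch outside recording"
      next
    }
    if (!is.null(mask) &&
        any(mask@mask[chSel, idx, drop = FALSE])) {
      reasons[i] <- "artifact overlap"
      next
    }
    keep[i] <- TRUE
    segs[[i]] <- recording@data[chSel, idx, drop = FALSE]
  }
  kept <- which(keep)
  if (!length(kept)) stop("all epochs rejected")
  dat <- array(0, c(length(kept), length(chSel), nT))
  for (k in seq_along(kept)) dat[k, , ] <- segs[[kept[k]]]

  ti <- as.data.frame(schedule)[kept, , drop = FALSE]
  rej <- data.frame(trial = which(!keep), reason = reasons[!keep])

  excl <- c()
  for (grp in list(ti$valence, ti$role)) {
    tb <- table(factor(grp))
    excl <- c(excl, stats::setNames(tb < minTrials, names(tb)))
  }
  new("EpochArray", data = dat, times = tIdx / fs, samplingRate = fs,
      channelInfo = recording@channelInfo[chSel, , drop = FALSE],
      trialInfo = ti, rejected = rej, excluded = excl)
}
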