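#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib extinctRSA, .registration = TRUE
NULL

#' Multichannel iEEG recording
#'
#' Container for a continuous multichannel voltage recording with event
#' markers. Channels are rows of \code{data}; \code{channelInfo} carries the
#' electrode-shaft grouping and ROI tag needed for bipolar referencing and
#' ROI-level epoching.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelInfo data.frame with columns \code{channel}, \code{shaft},
#'   \code{contact} (within-shaft order, 1 = deepest) and \code{roi}.
#' @slot events data.frame with columns \code{sample}, \code{marker}
#'   (\code{"video"}, \code{"cue"}, \code{"us"}), \code{phase} and
#'   \code{trial} (1-based index within phase).
#' @slot processing character log of processing steps applied.
#' @exportClass Recording
setClass("Recording",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channelInfo = "data.frame",
    events = "data.frame",
    processing = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@data) != nrow(object@channelInfo))
    msg <- c(msg, "channelInfo rows must match the number of data rows")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  need <- c("channel", "shaft", "contact", "roi")
  if (!all(need %in% names(object@channelInfo)))
    msg <- c(msg, paste("channelInfo must have columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@events) > 0) {
    if (!all(c("sample", "marker", "phase", "trial") %in% names(object@events)))
      msg <- c(msg, "events must have columns sample, marker, phase, trial")
    else if (any(object@events$sample < 1 |
                 object@events$sample > ncol(object@data)))
      msg <- c(msg, "event samples must lie within the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Artifact mask
#'
#' Boolean channels x samples mask of artifactual samples, padded by
#' \code{padSeconds} around each detected core sample.
#'
#' @slot mask logical matrix, channels x samples.
#' @slot thresholds named numeric vector of the z thresholds used.
#' @slot padSeconds padding applied around core samples, in seconds.
#' @slot samplingRate sampling rate of the underlying recording (Hz).
#' @exportClass ArtifactMask
setClass("ArtifactMask",
  representation(
    mask = "matrix",
    thresholds = "numeric",
    padSeconds = "numeric",
    samplingRate = "numeric"
  )
)

#' Epoched voltage data
#'
#' Trials x channels x time array of cue-locked voltage segments, with the
#' retained-trial metadata and a ledger of rejected trials.
#'
#' @slot data numeric array trials x channels x time.
#' @slot times time axis in seconds relative to cue onset.
#' @slot samplingRate Hz.
#' @slot channelInfo data.frame as in \linkS4class{Recording}.
#' @slot trialInfo data.frame of the retained trials (schedule rows).
#' @slot rejected data.frame ledger (trial index, reason).
#' @slot excluded named logical: condition contrasts for which the
#'   participant falls below the minimum trial count.
#' @exportClass EpochArray
setClass("EpochArray",
  representation(
    data = "array",
    times = "numeric",
    samplingRate = "numeric",
    channelInfo = "data.frame",
    trialInfo = "data.frame",
    rejected = "data.frame",
    excluded = "logical"
  )
)

setValidity("EpochArray", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x time array")
  else {
    if (d[3] != length(object@times))
      msg <- c(msg, "time axis length must match dim(data)[3]")
    if (d[1] != nrow(object@trialInfo))
      msg <- c(msg, "trialInfo rows must match dim(data)[1]")
    if (d[2] != nrow(object@channelInfo))
      msg <- c(msg, "channelInfo rows must match dim(data)[2]")
  }
  if (length(msg)) msg else TRUE
})

#' Time-frequency power tensor
#'
#' Trials x channels x frequencies x time array of Morlet wavelet power with
#' its frequency grid and normalization state.
#'
#' @slot power numeric array trials x channels x frequencies x time.
#' @slot freqs frequencies in Hz.
#' @slot cycles wavelet cycles per frequency.
#' @slot times output time instants in seconds (cue-locked).
#' @slot normalization \code{"raw"} or \code{"zscored"}.
#' @slot reference short description of the z-scoring reference set.
#' @slot channelInfo data.frame for the channel axis.
#' @slot trialInfo data.frame for the trial axis.
#' @exportClass TFRArray
setClass("TFRArray",
  representation(
    power = "array",
    freqs = "numeric",
    cycles = "numeric",
    times = "numeric",
    normalization = "character",
    reference = "character",
    channelInfo = "data.frame",
    trialInfo = "data.frame"
  )
)

setValidity("TFRArray", function(object) {
  d <- dim(object@power)
  msg <- character()
  if (length(d) != 4L)
    msg <- c(msg, "power must be a 4-d array (trials, channels, freqs, times)")
  else {
    if (d[3] != length(object@freqs)) msg <- c(msg, "freqs length mismatch")
    if (d[4] != length(object@times)) msg <- c(msg, "times length mismatch")
    if (length(object@cycles) != length(object@freqs))
      msg <- c(msg, "cycles must parallel freqs")
  }
  if (!object@normalization %in% c("raw", "zscored"))
    msg <- c(msg, "normalization must be 'raw' or 'zscored'")
  if (length(msg)) msg else TRUE
})

#' Sliding-window spectral-spatial pattern series
#'
#' Per-trial feature vectors (channels x frequencies, flattened) in sliding
#' windows, the substrate for representational similarity analysis.
#'
#' @slot features numeric array trials x features x windows.
#' @slot centers window-center times in seconds.
#' @slot lock \code{"cue"} or \code{"video"}.
#' @slot trialInfo data.frame for the trial axis.
#' @exportClass PatternSeries
setClass("PatternSeries",
  representation(
    features = "array",
    centers = "numeric",
    lock = "character",
    trialInfo = "data.frame"
  )
)

#' Cluster-based permutation test result
#'
#' Observed clusters with corrected p values plus the permutation null of
#' maximum cluster masses.
#'
#' @slot statMap observed statistic map (matrix; 1 x n for 1D tests).
#' @slot clusters data.frame: cluster id, sign, mass, n bins, corrected p,
#'   and (for axis-labelled maps) extents.
#' @slot labels integer matrix of cluster membership (0 = none).
#' @slot nullMax numeric vector of permutation max |cluster mass|.
#' @slot nPerm number of permutations.
#' @slot clusterAlpha cluster-forming alpha (two-tailed).
#' @slot threshold the statistic threshold corresponding to clusterAlpha.
#' @slot scheme permutation scheme descriptor.
#' @slot seed RNG seed used.
#' @slot rowValues,colValues axis values of the map (e.g. Hz, seconds).
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(
    statMap = "matrix",
    clusters = "data.frame",
    labels = "matrix",
    nullMax = "numeric",
    nPerm = "numeric",
    clusterAlpha = "numeric",
    threshold = "numeric",
    scheme = "character",
    seed = "numeric",
    rowValues = "numeric",
    colValues = "numeric"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  if (nrow(object@clusters) > 0) {
    p <- object@clusters$p
    if (any(p < 1 / (object@nPerm + 1) - 1e-12 | p > 1))
      msg <- c(msg, "corrected p values must lie in [1/(nPerm+1), 1]")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn Recording-class number of channels
#' @param object a \code{Recording}
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @export
setMethod("nChannels", "Recording", function(object) nrow(object@data))
#' @export
setMethod("nChannels", "EpochArray", function(object) dim(object@data)[2])

#' Sampling rate accessor
#' @param object an object with a sampling rate
#' @return sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "Recording", function(object) object@samplingRate)
#' @export
setMethod("samplingRate", "EpochArray", function(object) object@samplingRate)

#' Channel metadata accessor
#' @param object an object carrying channel metadata
#' @return data.frame of channel metadata
#' @export
setGeneric("channelInfo", function(object) standardGeneric("channelInfo"))
#' @export
setMethod("channelInfo", "Recording", function(object) object@channelInfo)
#' @export
setMethod("channelInfo", "EpochArray", function(object) object@channelInfo)
#' @export
setMethod("channelInfo", "TFRArray", function(object) object@channelInfo)

#' Trial metadata accessor
#' @param object an object carrying trial metadata
#' @return data.frame of trial metadata (one row per retained trial)
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @export
setMethod("trialInfo", "EpochArray", function(object) object@trialInfo)
#' @export
setMethod("trialInfo", "TFRArray", function(object) object@trialInfo)
#' @export
setMethod("trialInfo", "PatternSeries", function(object) object@trialInfo)

#' Cluster table accessor
#' @param object a \code{ClusterTestResult}
#' @return data.frame of observed clusters with corrected p values
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))
#' @export
setMethod("clusters", "ClusterTestResult", function(object) object@clusters)

## ---- show methods ----

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  rois <- table(object@channelInfo$roi)
  cat("  ROIs:", paste(sprintf("%s(%d)", names(rois), rois), collapse = " "),
      "\n")
  cat(sprintf("  events: %d | processing: %s\n", nrow(object@events),
              if (length(object@processing)) {
                paste(object@processing, collapse = " > ")
              } else "raw"))
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochArray: %d trials x %d channels x %d samples [%g, %g] s @ %g Hz\n",
    d[1], d[2], d[3], min(object@times), max(object@times),
    object@samplingRate))
  cat(sprintf("  rejected trials: %d\n", nrow(object@rejected)))
})

setMethod("show", "TFRArray", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "TFRArray (%s): %d trials x %d channels x %d freqs [%g-%g Hz] x %d times\n",
    object@normalization, d[1], d[2], d[3], min(object@freqs),
    max(object@freqs), d[4]))
})

setMethod("show", "PatternSeries", function(object) {
  d <- dim(object@features)
  cat(sprintf(
    "PatternSeries (%s-locked): %d trials x %d features x %d windows\n",
    object@lock, d[1], d[2], d[3]))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "ClusterTestResult: %d cluster(s), %d permutations, cluster alpha %g\n",
    nrow(object@clusters), object@nPerm, object@clusterAlpha))
  if (nrow(object@clusters)) {
    sig <- object@clusters[object@clusters$p <= 0.05, , drop = FALSE]
    cat(sprintf("  significant at p <= 0.05: %d\n", nrow(sig)))
  }
})

setMethod("show", "ArtifactMask", function(object) {
  cat(sprintf("ArtifactMask: %d channels x %d samples, %.2f%% flagged\n",
              nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask)))
})
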