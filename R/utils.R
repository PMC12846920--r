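# Internal numerical helpers: frequency-domain zero-phase filtering, small
# linear-algebra utilities, and rank/correlation primitives shared by the
# similarity modules.

# FFT length with small prime factors at or above n.
.goodFFTLength <- function(n) {
  stats::nextn(n, c(2, 3, 5))
}

# Squared-magnitude Butterworth responses evaluated on a frequency axis.
# Applying these once in the frequency domain is zero-phase and equals the
# forward-backward (filtfilt) application of the corresponding IIR filter in
# the long-record limit.
.butterLowpassH2 <- function(f, fc, order = 4) {
  1 / (1 + (f / fc)^(2 * order))
}

.butterHighpassH2 <- function(f, fc, order = 4) {
  r <- (fc / f)^(2 * order)
  h <- 1 / (1 + r)
  h[f == 0] <- 0
  h
}

.butterBandstopH2 <- function(f, flo, fhi, order = 4) {
  f0sq <- flo * fhi
  bw <- fhi - flo
  num <- bw * f
  den <- f0sq - f^2
  ratio <- ifelse(den == 0, Inf, num / den)
  1 / (1 + ratio^(2 * order))
}

# Cache of evaluated |H|^2 responses keyed by length/rate/parameter string.
.h2Cache <- new.env(parent = emptyenv())

# Apply a product of squared-magnitude responses to each row of a channels x
# samples matrix via FFT. `h2fun(freqAxis)` must return the combined |H|^2;
# `key` (optional) memoises the evaluated response.
.fftFilterRows <- function(x, samplingRate, h2fun, key = NULL) {
  n <- ncol(x)
  nfft <- .goodFFTLength(n)
  h2 <- NULL
  fullKey <- if (!is.null(key)) paste(key, nfft, samplingRate, sep = "|")
  if (!is.null(fullKey)) h2 <- .h2Cache[[fullKey]]
  if (is.null(h2)) {
    freqs <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) *
      samplingRate / nfft
    h2 <- h2fun(abs(freqs))
    if (!is.null(fullKey)) .h2Cache[[fullKey]] <- h2
  }
  out <- x
  for (i in seq_len(nrow(x))) {
    xp <- c(x[i, ], rep(0, nfft - n))
    xf <- stats::fft(xp) * h2
    out[i, ] <- Re(stats::fft(xf, inverse = TRUE))[seq_len(n)] / nfft
  }
  out
}

# Fused filtering: one forward FFT per row, two inverse transforms, giving
# the band/notch-filtered signal and the 250 Hz high-passed signal used by
# the artifact detector. Equivalent to calling .fftFilterRows twice.
.fftFilterPair <- function(x, samplingRate, h2band, h2hf) {
  n <- ncol(x)
  nfft <- .goodFFTLength(n)
  filt <- x; hf <- x
  for (i in seq_len(nrow(x))) {
    xf <- stats::fft(c(x[i, ], rep(0, nfft - n)))
    filt[i, ] <- Re(stats::fft(xf * h2band, inverse = TRUE))[seq_len(n)] /
      nfft
    hf[i, ] <- Re(stats::fft(xf * h2hf, inverse = TRUE))[seq_len(n)] / nfft
  }
  list(filtered = filt, hf = hf)
}

# Evaluate (and memoise) an |H|^2 response on the two-sided FFT axis.
.evalH2 <- function(n, samplingRate, h2fun, key) {
  nfft <- .goodFFTLength(n)
  fullKey <- paste(key, nfft, samplingRate, sep = "|")
  h2 <- .h2Cache[[fullKey]]
  if (is.null(h2)) {
    freqs <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) *
      samplingRate / nfft
    h2 <- h2fun(abs(freqs))
    .h2Cache[[fullKey]] <- h2
  }
  h2
}

# Fisher z transform with clamping of perfect correlations.
.RHO_CLAMP <- 1 - 1e-12

#' Fisher z transform of a correlation coefficient
#'
#' Applies \code{atanh} after clamping rho to +/- (1 - 1e-12) so that perfect
#' correlations map to a large finite value rather than +/- Inf.
#'
#' @param rho numeric vector of correlation coefficients in [-1, 1] (values
#'   outside are clamped); NAs pass through.
#' @return numeric vector of Fisher z values.
#' @examples
#' fisherZ(0.5)  # atanh(0.5) = 0.5493
#' @export
fisherZ <- function(rho) {
  atanh(pmin(pmax(rho, -.RHO_CLAMP), .RHO_CLAMP))
}

#' Bonferroni-corrected alpha level
#'
#' @param alpha nominal alpha.
#' @param k number of comparisons (here typically the 5 ROIs).
#' @return corrected alpha \code{alpha / k}.
#' @examples
#' bonferroniAlpha(0.05, 5)  # 0.01
#' @export
bonferroniAlpha <- function(alpha, k) {
  stopifnot(k >= 1, alpha > 0, alpha <= 1)
  alpha / k
}

# Column ranks (average rank for ties) of a matrix, vectorized over columns.
.colRanks <- function(x) {
  apply(x, 2, rank, ties.method = "average")
}

# Spearman correlation matrix between columns of A and columns of B across
# rows (observations). Zero-variance columns give NA.
.spearmanCross <- function(a, b) {
  ra <- .colRanks(a)
  rb <- .colRanks(b)
  suppressWarnings(stats::cor(ra, rb))
}

# Center and scale rank matrix columns to unit norm; zero-variance -> NA col.
.rankScale <- function(x) {
  r <- .colRanks(as.matrix(x))
  r <- sweep(r, 2, colMeans(r))
  nrm <- sqrt(colSums(r^2))
  nrm[nrm == 0] <- NA_real_
  sweep(r, 2, nrm, "/")
}

# Paired and one-sample t maps over participants (rows = participants).
.oneSampleT <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt(pmax(colMeans(x^2) - m^2, 0) * n / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  t
}

.pairedT <- function(a, b) .oneSampleT(a - b)

# Derive a substream seed from a master seed (kept below 2^31).
.childSeed <- function(seed, k) {
  (as.double(seed) * 48271 + 1103 * k) %% 2147483647
}

# One-sample t test tolerant of zero-variance input (all values equal):
# a nonzero constant is infinitely significant, zero is null.
.safeTTest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n >= 2 && stats::sd(x) > 0) {
    tt <- stats::t.test(x)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, n = n))
  }
  m <- if (n) mean(x) else NA_real_
  list(t = if (!is.na(m) && m != 0) sign(m) * Inf else 0,
       df = n - 1, p = if (!is.na(m) && m != 0) 0 else 1, n = n)
}
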