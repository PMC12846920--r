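makeEpochs <- function(data, fs = 1000, times = seq(-3, 4, by = 1 / fs)) {
  nCh <- dim(data)[2]
  new("EpochArray", data = data, times = times, samplingRate = fs,
      channelInfo = data.frame(channel = paste0("c", seq_len(nCh)),
                               shaft = "s", contact = seq_len(nCh),
                               roi = "AMY"),
      trialInfo = data.frame(index = seq_len(dim(data)[1])),
      rejected = data.frame(trial = integer(), reason = character()),
      excluded = logical())
}

test_that("the frequency grid has the variable-cycle layout", {
  g <- buildFrequencyGrid()
  expect_length(g$freqs, 44)
  expect_equal(g$cycles[g$freqs == 1], 3)
  expect_equal(g$cycles[g$freqs == 29], 6)
  expect_equal(g$cycles[g$freqs == 30], 6)
  expect_equal(g$cycles[g$freqs == 100], 12)
  expect_equal(g$cycles[g$freqs == 15], 4.5)
  expect_equal(g$cycles[g$freqs == 65], 9)
})

test_that("wavelet power peaks at the stimulus frequency and scales as a^2", {
  fs <- 1000
  times <- seq(-3, 4, by = 1 / fs)
  peaks <- c()
  pw6 <- c()
  for (a in c(1, 2, 4)) {
    x <- a * sin(2 * pi * 6 * times)
    dat <- array(x, c(1, 1, length(times)))
    tf <- morletTFR(makeEpochs(dat), freqRange = c(1, 20),
                    window = c(0.2, 1.5), timeStep = 0.05)
    spec <- apply(tf@power[1, 1, , ], 1, mean)
    peaks <- c(peaks, tf@freqs[which.max(spec)])
    pw6 <- c(pw6, spec[tf@freqs == 6])
  }
  expect_true(all(abs(peaks - 6) <= 1))
  slope <- coef(lm(log(pw6) ~ log(c(1, 2, 4))))[2]
  expect_lt(abs(slope - 2), 0.05)
})

test_that("white-noise power is flat over time and zero input gives zero", {
  set.seed(9)
  dat <- array(rnorm(40 * 1 * 7001), c(40, 1, 7001))
  tf <- morletTFR(makeEpochs(dat), freqRange = c(4, 30),
                  window = c(0, 1.5), timeStep = 0.1)
  for (fi in seq_along(tf@freqs)) {
    m <- apply(tf@power[, 1, fi, ], 2, mean)
    se <- apply(tf@power[, 1, fi, ], 2, sd) / sqrt(40)
    frac <- mean(abs(m - mean(m)) <= 2 * se)
    expect_gte(frac, 0.7)
  }
  tf0 <- morletTFR(makeEpochs(array(0, c(2, 1, 7001))),
                   freqRange = c(1, 12), window = c(0, 1))
  expect_true(all(tf0@power == 0))
})

test_that("edge-contaminated output times are refused or marked", {
  dat <- array(rnorm(2 * 1 * 7001), c(2, 1, 7001))
  ep <- makeEpochs(dat)
  expect_error(morletTFR(ep, freqRange = c(1, 2), window = c(-2.5, 0)),
               "edge")
  tf <- morletTFR(ep, freqRange = c(1, 2), window = c(-2.5, 0),
                  edge = "na")
  expect_true(anyNA(tf@power))
})

test_that("z-scoring matches a brute-force oracle and is shift-invariant", {
  pw <- array(c(1, 3, 2, 6, 4, 5), c(2, 1, 1, 3))
  tf <- new("TFRArray", power = pw, freqs = 5, cycles = 4,
            times = c(0.1, 0.2, 0.3), normalization = "raw",
            reference = "",
            channelInfo = data.frame(channel = "c1", shaft = "s",
                                     contact = 1, roi = "AMY"),
            trialInfo = data.frame(index = 1:2))
  z <- zscorePower(tf)
  vals <- as.numeric(pw)
  expect_equal(as.numeric(z@power),
               (vals - mean(vals)) / sd(vals))

  tf2 <- tf
  tf2@power <- tf@power + 7
  z2 <- zscorePower(tf2)
  expect_equal(z@power, z2@power)

  tfc <- tf
  tfc@power[] <- 3
  expect_error(zscorePower(tfc), "zero reference SD")
})

test_that("z-scoring then contrasting is invariant to per-channel gain", {
  set.seed(4)
  pw <- array(abs(rnorm(10 * 2 * 3 * 4)), c(10, 2, 3, 4))
  mk <- function(p) new("TFRArray", power = p, freqs = c(4, 6, 8),
                        cycles = c(3, 3.5, 4), times = (1:4) / 10,
                        normalization = "raw", reference = "",
                        channelInfo = data.frame(
                          channel = c("c1", "c2"), shaft = "s",
                          contact = 1:2, roi = "AMY"),
                        trialInfo = data.frame(index = 1:10))
  z1 <- zscorePower(mk(pw))
  pw2 <- pw
  pw2[, 2, , ] <- pw[, 2, , ] * 16  # channel gain (power scale)
  z2 <- zscorePower(mk(pw2))
  expect_equal(z1@power, z2@power, tolerance = 1e-12)
})

test_that("identical condition data yield a zero t map with no clusters", {
  set.seed(5)
  base <- array(rnorm(8 * 1 * 3 * 4), c(8, 1, 3, 4))
  pw <- array(0, c(16, 1, 3, 4))
  pw[1:8, , , ] <- base
  pw[9:16, , , ] <- base
  tf <- new("TFRArray", power = pw, freqs = c(4, 6, 8),
            cycles = c(3, 3.5, 4), times = (1:4) / 10,
            normalization = "zscored", reference = "self",
            channelInfo = data.frame(channel = "c1", shaft = "s",
                                     contact = 1, roi = "AMY"),
            trialInfo = data.frame(index = 1:16))
  labels <- rep(c("CS+", "CS-"), each = 8)
  res <- tfConditionContrast(list(tf, tf, tf), list(labels, labels, labels),
                             freqRange = c(1, 12), window = c(0, 1),
                             nPerm = 200, seed = 1, minTrials = 8)
  expect_true(all(res$tmap == 0))
  expect_equal(nrow(clusters(res$test)), 0)
})

test_that("cluster-mean power reduces to hand-computed means", {
  pw <- array(seq_len(2 * 1 * 2 * 3), c(2, 1, 2, 3))
  tf <- new("TFRArray", power = pw, freqs = c(4, 6), cycles = c(3, 3.5),
            times = (1:3) / 10, normalization = "zscored",
            reference = "self",
            channelInfo = data.frame(channel = "c1", shaft = "s",
                                     contact = 1, roi = "AMY"),
            trialInfo = data.frame(index = 1:2))
  single <- matrix(FALSE, 2, 3); single[2, 1] <- TRUE
  expect_equal(as.numeric(clusterMeanPower(tf, single)),
               c(pw[1, 1, 2, 1], pw[2, 1, 2, 1]))
  quad <- matrix(FALSE, 2, 3); quad[1:2, 1:2] <- TRUE
  expect_equal(as.numeric(clusterMeanPower(tf, quad)),
               c(mean(pw[1, 1, 1:2, 1:2]), mean(pw[2, 1, 1:2, 1:2])))
  zeros <- tf; zeros@power[] <- 0
  expect_equal(as.numeric(clusterMeanPower(zeros, quad)), c(0, 0))
  expect_error(clusterMeanPower(tf, matrix(FALSE, 2, 3)), "empty")

  wz <- clusterMeanPower(tf, quad, labels = c("a", "b"),
                         zscoreWithinCondition = TRUE)
  expect_true(attr(wz, "zscoredWithinCondition"))
})

test_that("condition baseline tests recover planted deviations from zero", {
  set.seed(7)
  scalars <- lapply(1:10, function(i) {
    c(rnorm(12, 0.5, 0.2), rnorm(12, 0, 0.2))
  })
  labels <- lapply(1:10, function(i) rep(c("CS+", "CS-"), each = 12))
  res <- conditionBaselineTest(scalars, labels)
  expect_lt(res$p[res$condition == "CS+"], 0.01)
  expect_gt(res$p[res$condition == "CS-"], 0.05)
})
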