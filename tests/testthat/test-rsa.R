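test_that("feature vectors have ROI x frequency length and 90% overlap", {
  set.seed(1)
  pw <- array(rnorm(5 * 1 * 44 * 36), c(5, 1, 44, 36))
  tf <- new("TFRArray", power = pw, freqs = buildFrequencyGrid()$freqs,
            cycles = buildFrequencyGrid()$cycles,
            times = seq(0, 1.75, by = 0.05), normalization = "zscored",
            reference = "self",
            channelInfo = data.frame(channel = "c1", shaft = "s",
                                     contact = 1, roi = "AMY"),
            trialInfo = data.frame(index = 1:5))
  ps <- buildFeatureVectors(tf)
  expect_equal(dim(ps@features)[2], 44)
  expect_equal(diff(ps@centers)[1], 0.05)
  # overlap = 1 - step / length
  expect_equal(1 - 0.05 / 0.5, 0.9)
  expect_equal(ps@centers[1], 0.25)

  # constant-in-time tensor -> identical vectors at all centers
  tfc <- tf
  tfc@power <- array(rep(rnorm(5 * 44), times = 36), c(5, 1, 44, 36))
  psc <- buildFeatureVectors(tfc)
  expect_equal(psc@features[, , 1], psc@features[, , dim(psc@features)[3]])

  expect_error(buildFeatureVectors(tf, range = c(1.5, 2.5)), "beyond")
  raw <- tf; raw@normalization <- "raw"
  expect_error(buildFeatureVectors(raw), "z-scored")
})

test_that("pairwise Spearman matches closed-form rank correlations", {
  feat <- array(0, c(2, 4, 1))
  feat[1, , 1] <- c(1, 2, 3, 4)
  feat[2, , 1] <- c(1, 2, 3, 5)
  expect_equal(pairwiseSpearman(makePatterns(feat))[1, 2, 1], 1)

  feat2 <- array(0, c(2, 3, 1))
  feat2[1, , 1] <- c(1, 2, 3)
  feat2[2, , 1] <- c(3, 2, 1)
  expect_equal(pairwiseSpearman(makePatterns(feat2))[1, 2, 1], -1)

  feat3 <- array(0, c(2, 4, 1))
  feat3[1, , 1] <- c(1, 2, 3, 4)
  feat3[2, , 1] <- c(2, 1, 4, 3)
  expect_equal(pairwiseSpearman(makePatterns(feat3))[1, 2, 1], 0.6)

  # zero-variance vector -> missing, not zero
  feat4 <- array(rnorm(3 * 4), c(3, 4, 1))
  feat4[2, , 1] <- 5
  sim <- pairwiseSpearman(makePatterns(feat4))
  expect_true(is.na(sim[1, 2, 1]))
  expect_false(is.na(sim[1, 3, 1]))
  expect_true(all(is.na(diag(sim[, , 1]))))
})

test_that("similarity is invariant to strictly monotone feature transforms", {
  set.seed(2)
  feat <- array(rnorm(6 * 10 * 3), c(6, 10, 3))
  s1 <- pairwiseSpearman(makePatterns(feat))
  s2 <- pairwiseSpearman(makePatterns(exp(feat)))
  expect_equal(s1, s2)
})

test_that("single-trial metrics match brute-force pair enumeration", {
  set.seed(3)
  n <- 8
  sch <- makeToySchedule(n = n, cues = rep(1:2, each = 4),
                         contexts = rep(c(1, 2), 4))
  feat <- array(rnorm(n * 12 * 2), c(n, 12, 2))
  sim <- pairwiseSpearman(makePatterns(feat))

  st <- singleTrialItemStability(sim, sch)
  for (t in 1:n) {
    for (k in 1:2) {
      others <- setdiff(which(sch$cue_id == sch$cue_id[t]), t)
      expect_equal(st[t, k], mean(fisherZ(sim[t, others, k])))
    }
  }

  cs <- singleTrialContextSpecificity(sim, sch)
  for (t in 1:n) {
    same <- setdiff(which(sch$context_id == sch$context_id[t]), t)
    diff <- which(sch$context_id != sch$context_id[t])
    expect_equal(cs[t, 1], mean(fisherZ(sim[t, same, 1])) -
                   mean(fisherZ(sim[t, diff, 1])))
  }

  # all-identical patterns -> context specificity 0
  featEq <- array(rep(rnorm(12), each = n), c(n, 12, 1))
  simEq <- pairwiseSpearman(makePatterns(featEq))
  csEq <- singleTrialContextSpecificity(simEq, sch)
  expect_true(all(abs(csEq) < 1e-9))

  # 2 trials of an item: single-trial value equals the mutual Fisher z
  sch2 <- makeToySchedule(n = 4, cues = c(1, 1, 2, 2),
                          contexts = c(1, 2, 1, 2))
  feat2 <- array(rnorm(4 * 10 * 1), c(4, 10, 1))
  sim2 <- pairwiseSpearman(makePatterns(feat2))
  st2 <- singleTrialItemStability(sim2, sch2)
  expect_equal(st2[1, 1], fisherZ(sim2[1, 2, 1]))
  expect_equal(st2[2, 1], fisherZ(sim2[1, 2, 1]))
})

test_that("trial means of single-trial stability equal the pair-set mean", {
  set.seed(4)
  sch <- makeToySchedule(n = 12, cues = rep(1:3, each = 4))
  feat <- array(rnorm(12 * 15 * 2), c(12, 15, 2))
  sim <- pairwiseSpearman(makePatterns(feat))
  st <- singleTrialItemStability(sim, sch)
  for (cue in 1:3) {
    rows <- which(sch$cue_id == cue)
    z <- fisherZ(sim[rows, rows, 1])
    expect_equal(mean(st[rows, 1]), mean(z[upper.tri(z) | lower.tri(z)]))
  }
})

test_that("item stability contrast recovers planted class differences", {
  parts <- lapply(1:6, function(i) {
    makeRsaParticipant(100 + i, cueGain = 0.8, nWin = 8)
  })
  res <- itemStabilityContrast(lapply(parts, `[[`, "sim"),
                               lapply(parts, `[[`, "sched"),
                               nPerm = 300, seed = 1)
  cl <- clusters(res$test)
  expect_true(any(cl$p <= 0.05 & cl$sign == "positive"))
  # per-item-then-average rule: class series equal the mean of item rows
  p1 <- res$perItem[[1]]
  sch <- parts[[1]]$sched
  val <- tapply(sch$valence, sch$cue_id, function(x) x[1])
  minusRows <- which(val[rownames(p1)] == "CS-")
  expect_equal(res$csMinus[1, ], colMeans(p1[minusRows, , drop = FALSE]))
})

test_that("perfectly stable distinct items reach the clamped maximum", {
  sch <- makeToySchedule(n = 6, cues = rep(1:3, each = 2),
                         contexts = rep(1:2, 3))
  base <- matrix(rnorm(3 * 10), 3)
  feat <- array(0, c(6, 10, 1))
  for (t in 1:6) feat[t, , 1] <- base[sch$cue_id[t], ]
  sim <- pairwiseSpearman(makePatterns(feat))
  st <- singleTrialItemStability(sim, sch)
  expect_equal(st[1, 1], fisherZ(1), tolerance = 1e-6)
})

test_that("context specificity is null for permuted labels and flags low pairs", {
  parts <- lapply(1:6, function(i) makeRsaParticipant(200 + i, nWin = 6))
  res <- contextSpecificityContrast(lapply(parts, `[[`, "sim"),
                                    lapply(parts, `[[`, "sched"),
                                    nPerm = 200, seed = 2)
  # no planted context structure: group means near zero
  gm <- colMeans(res$diff)
  se <- apply(res$diff, 2, sd) / sqrt(nrow(res$diff))
  expect_true(mean(abs(gm) <= 2 * se) >= 0.5)
  cl <- clusters(res$test)
  expect_true(nrow(cl) == 0 || min(cl$p) > 0.05)

  # different-cue restriction produces a valid result too
  res2 <- contextSpecificityContrast(lapply(parts, `[[`, "sim"),
                                     lapply(parts, `[[`, "sched"),
                                     nPerm = 100, seed = 3,
                                     pairSet = "different-cue")
  expect_equal(ncol(res2$diff), 6)
})

test_that("metric series export to tidy TSV", {
  m <- matrix(1:6, 2, 3)
  attr(m, "centers") <- c(0.25, 0.3, 0.35)
  path <- tempfile(fileext = ".tsv")
  writeMetricTSV(list(m, m * 2), path, roi = "AMY")
  tab <- read.delim(path)
  expect_equal(nrow(tab), 12)
  expect_setequal(unique(tab$time), c(0.25, 0.3, 0.35))
  expect_equal(tab$value[tab$participant == 1 & tab$trial == 2 &
                           tab$time == 0.3], 4)
})
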