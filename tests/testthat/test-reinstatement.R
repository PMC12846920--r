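mkPhasePatterns <- function(sch, base = NULL, noise = 1, nFeat = 12,
                            nWin = 4, seed = 1) {
  set.seed(seed)
  n <- nrow(sch)
  feat <- array(rnorm(n * nFeat * nWin, sd = noise), c(n, nFeat, nWin))
  if (!is.null(base)) {
    for (t in seq_len(n)) feat[t, , ] <- feat[t, , ] + base[sch$cue_id[t], ]
  }
  makePatterns(feat, centers = seq(0.7, by = 0.05, length.out = nWin),
               trialInfo = as.data.frame(sch))
}

test_that("cross-phase similarity matches brute-force Spearman", {
  schA <- makeToySchedule(n = 2, phase = "acquisition", cues = c(1, 2),
                          contexts = c(1, 2))
  schT <- makeToySchedule(n = 2, phase = "test", cues = c(1, 2),
                          contexts = c(9, 10))
  pa <- mkPhasePatterns(schA, seed = 2)
  pt <- mkPhasePatterns(schT, seed = 3)
  sim <- crossPhaseSimilarity(pa, pt)
  for (i in 1:2) for (j in 1:2) for (k in 1:4) {
    expect_equal(sim[i, j, k],
                 cor(pa@features[i, , k], pt@features[j, , k],
                     method = "spearman"))
  }
})

test_that("identical acquisition and test patterns reach the clamped max", {
  sch <- makeToySchedule(n = 6, phase = "acquisition",
                         cues = rep(1:3, 2), contexts = rep(1:2, 3))
  schT <- sch; schT$phase <- "test"
  base <- matrix(rnorm(3 * 12), 3)
  pa <- mkPhasePatterns(sch, base = base, noise = 0, seed = 4)
  pt <- mkPhasePatterns(schT, base = base, noise = 0, seed = 5)
  simAT <- crossPhaseSimilarity(pa, pt)
  rec <- reinstatementRecord(simAT, simAT, sch, sch, schT,
                             window = c(0.7, 0.9))
  expect_equal(rec$reinstAcq, rep(fisherZ(1), 3), tolerance = 1e-6)
  expect_equal(rec$reinst, rep(0, 3))
})

test_that("differential reinstatement is antisymmetric and additive", {
  sch <- makeToySchedule(n = 6, phase = "extinction",
                         cues = rep(1:3, 2), contexts = rep(1:2, 3))
  schT <- sch; schT$phase <- "test"
  # constant-similarity toys: acquisition rho 0.3, extinction rho 0.1
  simA <- array(0.3, c(6, 6, 2)); attr(simA, "centers") <- c(0.8, 0.85)
  simE <- array(0.1, c(6, 6, 2)); attr(simE, "centers") <- c(0.8, 0.85)
  rec <- reinstatementRecord(simA, simE, sch, sch, schT,
                             window = c(0.8, 0.85))
  expect_equal(rec$reinst, rep(fisherZ(0.3) - fisherZ(0.1), 3),
               tolerance = 1e-10)
  swapped <- reinstatementRecord(simE, simA, sch, sch, schT,
                                 window = c(0.8, 0.85))
  expect_equal(swapped$reinst, -rec$reinst)

  dr <- differentialReinstatement(list(rec, swapped))
  expect_equal(unname(dr$roleMeans), rep(0, 3))
})

test_that("trial reinstatement matches brute-force pair averaging", {
  schE <- makeToySchedule(n = 4, phase = "extinction",
                          cues = c(1, 1, 2, 2), contexts = c(1, 2, 1, 2))
  schT <- makeToySchedule(n = 4, phase = "test", cues = c(1, 2, 1, 2),
                          contexts = c(9, 10, 9, 10))
  pe <- mkPhasePatterns(schE, seed = 6)
  pt <- mkPhasePatterns(schT, seed = 7)
  sim <- crossPhaseSimilarity(pe, pt)
  tr <- trialReinstatement(sim, schE, schT, window = c(0.7, 0.9))
  cols <- which(attr(sim, "centers") >= 0.7 & attr(sim, "centers") <= 0.9)
  for (j in 1:4) {
    same <- which(schE$cue_id == schT$cue_id[j])
    diffI <- which(schE$cue_id != schT$cue_id[j])
    expect_equal(unname(tr[j]),
                 mean(apply(fisherZ(sim[, , cols]), c(1, 2), mean)[same, j]) -
                   mean(apply(fisherZ(sim[, , cols]),
                              c(1, 2), mean)[diffI, j]))
  }
  expect_equal(attr(tr, "role"), schT$role)
})

test_that("participant-level coupling correlations are exact and guarded", {
  ctx <- c(0.01, 0.03, 0.02, 0.05, 0.04, 0.06, 0.00, 0.07)
  reinst <- cbind("CS++" = rnorm(8, 0, 0.1),
                  "CS+-" = ctx * 2 + 0.001,   # monotone coupling
                  "CS--" = rnorm(8, 0, 0.1))
  res <- contextVsReinstatementCorrelation(ctx, reinst)
  expect_equal(res$rho[res$role == "CS+-"], 1)
  expect_error(contextVsReinstatementCorrelation(ctx[1:4],
                                                 reinst[1:4, ]),
               "fewer than 5")
})

test_that("time-resolved coupling flags the coupled window", {
  set.seed(8)
  ctx <- rnorm(14)
  course <- matrix(rnorm(14 * 8, sd = 0.6), 14, 8)
  course[, 3:5] <- course[, 3:5] + ctx  # coupling at centers 3-5
  res <- contextVsReinstatementTimecourse(ctx, course,
                                          centers = (1:8) / 10,
                                          nPerm = 300, seed = 2)
  cl <- clusters(res$test)
  expect_true(any(cl$p <= 0.05 & cl$colMin <= 0.5 & cl$colMax >= 0.3))
})

test_that("rating couplings handle degenerate and missing data", {
  set.seed(9)
  mkPart <- function(couple) {
    role <- rep(c("CS++", "CS+-", "CS--"), each = 10)
    r <- rnorm(30)
    attr(r, "role") <- role
    ratings <- sample(1:4, 30, TRUE)
    if (couple) ratings[role == "CS+-"] <-
        round(2.5 + tanh(r[role == "CS+-"]) + rnorm(10, 0, 0.2))
    ratings <- pmin(4, pmax(1, ratings))
    list(r = r, ratings = ratings)
  }
  parts <- lapply(1:10, function(i) mkPart(couple = TRUE))
  res <- reinstatementVsRatings(lapply(parts, `[[`, "r"),
                                lapply(parts, `[[`, "ratings"))
  byRole <- res$byRole
  expect_lt(byRole$p[byRole$role == "CS+-"], 0.05)

  # constant ratings -> participant excluded (NA rho), not zero-filled
  p1 <- parts[[1]]
  p1$ratings[] <- 3
  resC <- reinstatementVsRatings(list(p1$r), list(p1$ratings))
  expect_true(all(is.na(resC$rho)))

  # outlier exclusion path with the stricter trial minimum
  res2 <- reinstatementVsRatings(lapply(parts, `[[`, "r"),
                                 lapply(parts, `[[`, "ratings"),
                                 outlierSD = 2, minTrials = 8)
  expect_true(is.data.frame(res2$byRole))
})
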