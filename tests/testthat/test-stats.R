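test_that("identical conditions give no clusters", {
  set.seed(1)
  data <- lapply(1:5, function(i) {
    x <- matrix(rnorm(10 * 12), 10, 12)
    rbind(x, x)
  })
  labels <- lapply(1:5, function(i) rep(c("a", "b"), each = 10))
  res <- clusterPermutation(data, labels, mapDim = c(3, 4), nPerm = 200,
                            seed = 1)
  expect_true(all(res@statMap == 0))
  expect_equal(nrow(clusters(res)), 0)
})

test_that("a strong contiguous effect is detected reliably", {
  hits <- 0
  nRun <- 100
  for (r in seq_len(nRun)) {
    set.seed(r)
    data <- list(); labels <- list()
    for (i in 1:15) {
      a <- matrix(rnorm(20 * 40), 20, 40)
      a[, 11:20] <- a[, 11:20] + 1       # 10-bin block, participant d ~ 3
      b <- matrix(rnorm(20 * 40), 20, 40)
      data[[i]] <- rbind(a, b)
      labels[[i]] <- rep(c("a", "b"), each = 20)
    }
    res <- clusterPermutation(data, labels, mapDim = 40, nPerm = 500,
                              seed = r)
    cl <- clusters(res)
    if (nrow(cl) && any(cl$p <= 0.05)) hits <- hits + 1
  }
  expect_gte(hits / nRun, 0.95)
})

test_that("cluster mass grows when an adjacent significant bin joins", {
  m1 <- matrix(c(3, 3, 0, 0, 0, 0), 1)
  m2 <- matrix(c(3, 3, 3, 0, 0, 0), 1)
  mass1 <- extinctRSA:::.labelClustersC(m1, 2)$masses
  mass2 <- extinctRSA:::.labelClustersC(m2, 2)$masses
  expect_gt(abs(mass2[1]), abs(mass1[1]))
  # sign homogeneity: opposite-sign neighbours stay separate
  m3 <- matrix(c(3, -3, 3), 1)
  expect_length(extinctRSA:::.labelClustersC(m3, 2)$masses, 3)
  # 4-neighbourhood in 2D: diagonals do not connect
  m4 <- matrix(c(3, 0, 0, 3), 2)
  expect_length(extinctRSA:::.labelClustersC(m4, 2)$masses, 2)
})

test_that("the signed-rank wrapper agrees with exact enumeration", {
  exactP <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    obs <- sum(r[d > 0])
    stats <- vapply(0:(2^n - 1), function(m) {
      signs <- as.integer(intToBits(m))[1:n]
      sum(r[signs == 1])
    }, numeric(1))
    mu <- n * (n + 1) / 4
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(2)
  for (n in c(6, 8, 10)) {
    x <- rnorm(n)
    y <- rnorm(n)
    res <- signedRankTest(x, y)
    expect_equal(res$p.value, exactP(x - y), tolerance = 1e-10)
  }
})

test_that("learning-curve tests handle identical and divergent streams", {
  mkRatings <- function(n, onset = NULL) {
    do.call(rbind, lapply(1:n, function(p) {
      do.call(rbind, lapply(c("CS++", "CS+-"), function(role) {
        base <- if (is.null(onset) || role == "CS++") rep(2, 24) else
          c(rep(2, onset - 1), rep(4, 24 - onset + 1))
        data.frame(participant = p, phase = "extinction", role = role,
                   ordinal = 1:24,
                   rating = pmin(4, pmax(1, base + sample(-1:1, 24,
                                                          TRUE))))
      }))
    }))
  }
  set.seed(3)
  same <- mkRatings(12)
  same$rating[same$role == "CS+-"] <-
    same$rating[same$role == "CS++"]  # identical streams
  res <- learningCurveTest(same, "extinction", c("CS++", "CS+-"),
                           nPerm = 200, seed = 1)
  expect_true(all(res$p[!is.na(res$p)] == 1))
  expect_length(res$onsets, 0)

  div <- mkRatings(12, onset = 10)
  res2 <- learningCurveTest(div, "extinction", c("CS++", "CS+-"),
                            nPerm = 300, seed = 2)
  expect_gte(length(res2$onsets), 1)
  expect_lte(abs(min(res2$onsets) - 10), 3)
})

test_that("repeated-measures ANOVA matches a textbook decomposition", {
  # all cells equal -> all F = 0
  eq <- expand.grid(participant = 1:4, cue = c("A", "B", "C"),
                    phase = c("p1", "p2", "p3"))
  eq$rating <- 2
  res0 <- rmAnova2way(eq)
  expect_true(all(res0$effects$F == 0))

  # hand-built 3-participant table vs manual sums of squares
  set.seed(4)
  d <- expand.grid(participant = 1:3, cue = c("A", "B"),
                   phase = c("p1", "p2"))
  d$rating <- c(1, 2, 3, 2, 3, 5, 2, 1, 2, 4, 5, 7)
  res <- rmAnova2way(d)
  y <- xtabs(rating ~ participant + cue + phase, d)
  gm <- mean(y)
  ssCue <- 3 * 2 * sum((apply(y, 2, mean) - gm)^2)
  ssPhase <- 3 * 2 * sum((apply(y, 3, mean) - gm)^2)
  pc <- apply(y, c(1, 2), mean)
  errCue <- 2 * sum((pc - outer(apply(y, 1, mean), rep(1, 2)) -
                       outer(rep(1, 3), apply(y, 2, mean)) + gm)^2)
  fCue <- (ssCue / 1) / (errCue / 2)
  expect_equal(res$effects$F[res$effects$effect == "cue"], fCue,
               tolerance = 1e-8)
  expect_equal(res$effects$df1, c(1, 1, 1))
  expect_equal(res$effects$df2, c(2, 2, 2))
  expect_error(rmAnova2way(d[d$participant < 3, ]), "fewer than 3")
})

test_that("no interaction is declared when effects are additive", {
  fp <- 0
  for (r in 1:100) {
    set.seed(r)
    d <- expand.grid(participant = 1:12, cue = c("A", "B", "C"),
                     phase = c("p1", "p2", "p3"))
    cueEff <- c(A = 0, B = 0.5, C = 1)[d$cue]
    phEff <- c(p1 = 0, p2 = 0.3, p3 = 0.6)[d$phase]
    d$rating <- 2 + cueEff + phEff + rnorm(nrow(d), 0, 0.5)
    res <- rmAnova2way(d)
    if (res$effects$p[res$effects$effect == "cue:phase"] < 0.05)
      fp <- fp + 1
  }
  expect_lte(fp / 100, 0.10)
})

test_that("Fisher z and Bonferroni behave as specified", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5))
  expect_equal(round(fisherZ(0.5), 4), 0.5493)
  expect_true(is.finite(fisherZ(1)))
  expect_true(fisherZ(0.999) < fisherZ(0.9999))
  expect_equal(bonferroniAlpha(0.05, 5), 0.01)
  expect_error(bonferroniAlpha(0.05, 0))
})

test_that("permutation p values respect the positivity convention", {
  set.seed(6)
  data <- lapply(1:6, function(i) matrix(rnorm(16 * 10), 16, 10))
  labels <- lapply(1:6, function(i) rep(c("a", "b"), each = 8))
  res <- clusterPermutation(data, labels, mapDim = 10, nPerm = 200,
                            seed = 3)
  cl <- clusters(res)
  if (nrow(cl)) {
    expect_true(all(cl$p >= 1 / 201))
    expect_true(all(cl$p <= 1))
  }
  expect_match(res@scheme, "trial")
  expect_warning(clusterPermutation(data, labels, mapDim = 10, nPerm = 50,
                                    seed = 1), "100")
})
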