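test_that("phase schedules satisfy the design counts and US budget", {
  e <- generateExperiment(seed = 11)
  expect_equal(nrow(e$acquisition), 72)
  expect_equal(nrow(e$extinction), 72)
  expect_equal(nrow(e$test), 48)
  expect_false(any(e$test$us))
  total <- sum(e$acquisition$us) + sum(e$extinction$us) + sum(e$test$us)
  expect_equal(total, 36)
  # 50% reinforcement: each CS+ cue carries exactly 12 of 24 USs
  for (ph in c("acquisition", "extinction")) {
    s <- e[[ph]]
    for (cue in unique(s$cue_id)) {
      rows <- s[s$cue_id == cue, ]
      expect_equal(sum(rows$us),
                   if (rows$valence[1] == "CS+") 12 else 0)
    }
  }
})

test_that("roles are consistent across phases and context pools disjoint", {
  e <- generateExperiment(seed = 4)
  roleOf <- function(s) tapply(s$role, s$cue_id, function(x) x[1])
  expect_equal(roleOf(e$acquisition), roleOf(e$test))
  expect_equal(roleOf(e$extinction), roleOf(e$test))
  # exactly one cue flips valence at extinction (CS+- : CS+ -> CS-)
  vAcq <- tapply(e$acquisition$valence, e$acquisition$cue_id,
                 function(x) x[1])
  vExt <- tapply(e$extinction$valence, e$extinction$cue_id,
                 function(x) x[1])
  expect_equal(sum(vAcq != vExt), 1)
  ctx <- lapply(e[1:3], function(s) unique(s$context_id))
  expect_equal(lengths(ctx), c(acquisition = 4, extinction = 4, test = 8))
  expect_equal(length(Reduce(intersect, ctx)), 0)
})

test_that("run-length cap and context balance hold across seeds", {
  for (seed in 1:10) {
    e <- generateExperiment(seed = seed)
    for (s in e[1:3]) {
      expect_lte(max(rle(s$cue_id)$lengths), 3)
      tab <- table(s$cue_id, s$context_id)
      expect_lte(max(tab) - min(tab), 1)
      # ordinal-within-condition indexing is a bijection per cue
      ords <- ave(seq_len(nrow(s)), s$cue_id, FUN = seq_along)
      for (cue in unique(s$cue_id))
        expect_equal(sort(ords[s$cue_id == cue]),
                     seq_len(sum(s$cue_id == cue)))
    }
  }
})

test_that("schedules are deterministic per seed and vary across seeds", {
  a <- generateExperiment(seed = 21)
  b <- generateExperiment(seed = 21)
  expect_identical(a, b)
  c <- generateExperiment(seed = 22)
  expect_false(identical(a$extinction$cue_id, c$extinction$cue_id))
})

test_that("context assignment is independent of cue role", {
  # with exact balance the chi-square of context x cue contingency is 0,
  # so independence is never rejected
  reject <- 0
  for (seed in 1:200) {
    s <- generatePhaseSchedule("acquisition", seed = seed)
    p <- suppressWarnings(
      chisq.test(table(s$cue_id, s$context_id))$p.value)
    if (p < 0.01) reject <- reject + 1
  }
  expect_lte(reject / 200, 0.01)
})

test_that("validateSchedule reports violations and passes valid schedules", {
  s <- generatePhaseSchedule("test", seed = 2)
  expect_length(validateSchedule(s), 0)

  bad <- s
  bad$us[5] <- TRUE
  expect_true(any(grepl("US in test phase", validateSchedule(bad))))

  bad2 <- s
  bad2$cue_id[1:4] <- 2
  expect_true(any(grepl("run length > 3", validateSchedule(bad2))))
})

test_that("unsatisfiable constraints raise errors", {
  expect_error(designConfig(maxRunLength = 0), "maxRunLength")
  expect_error(designConfig(reinforcementRate = 0.3), "integer")
  expect_error(generatePhaseSchedule("acquisition",
                                     counterbalance = c("CS++" = 1,
                                                        "CS+-" = 1,
                                                        "CS--" = 3)),
               "bijection")
})

test_that("schedules round-trip through TSV", {
  s <- generatePhaseSchedule("acquisition", seed = 8)
  path <- tempfile(fileext = ".tsv")
  writeScheduleTSV(s, path)
  r <- readScheduleTSV(path)
  expect_equal(r$cue_id, s$cue_id)
  expect_equal(r$us, s$us)
})
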