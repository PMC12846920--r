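test_that("filtering attenuates notch bands and passes the passband", {
  fs <- 1000
  t <- seq_len(20 * fs) / fs
  mk <- function(x) {
    new("Recording", data = matrix(x, 1), samplingRate = fs,
        channelInfo = data.frame(channel = "c1", shaft = "s", contact = 1,
                                 roi = "AMY"),
        events = data.frame(sample = integer(), marker = character(),
                            phase = character(), trial = integer()),
        processing = character())
  }
  rms <- function(x) sqrt(mean(x^2))
  mid <- 5000:15000  # avoid edge transients
  f50 <- filterRecording(mk(sin(2 * pi * 50 * t)))
  expect_lt(rms(f50@data[1, mid]) / rms(sin(2 * pi * 50 * t[mid])), 0.1)
  f10 <- filterRecording(mk(sin(2 * pi * 10 * t)))
  expect_lt(abs(rms(f10@data[1, mid]) / rms(sin(2 * pi * 10 * t[mid])) - 1),
            0.1)
  fdc <- filterRecording(mk(rep(5, length(t))))
  expect_lt(rms(fdc@data[1, mid]), 0.5)

  slow <- mk(sin(2 * pi * 50 * t))
  slow@samplingRate <- 300
  expect_error(filterRecording(slow), "400")
})

test_that("bipolar referencing yields N-1 channels per shaft", {
  ci <- rbind(
    data.frame(channel = paste0("a", 1:8), shaft = "a", contact = 1:8,
               roi = "AMY"),
    data.frame(channel = paste0("b", 1:4), shaft = "b", contact = 1:4,
               roi = "HPC"),
    data.frame(channel = paste0("c", 1:6), shaft = "c", contact = 1:6,
               roi = "TMP"))
  set.seed(1)
  rec <- new("Recording", data = matrix(rnorm(18 * 1000), 18),
             samplingRate = 1000, channelInfo = ci,
             events = data.frame(sample = integer(), marker = character(),
                                 phase = character(), trial = integer()),
             processing = character())
  bip <- bipolarReference(rec)
  expect_equal(nrow(bip@data), 7 + 3 + 5)
  expect_equal(sum(bip@channelInfo$roi == "AMY"), 7)

  # common-mode removal
  rec2 <- rec
  rec2@data <- matrix(rep(rnorm(1000), each = 18), 18, byrow = FALSE)
  for (i in 1:18) rec2@data[i, ] <- rec2@data[1, ]
  bip2 <- bipolarReference(rec2)
  expect_true(all(abs(bip2@data) < 1e-12))

  ci3 <- rbind(ci, data.frame(channel = "d1", shaft = "d", contact = 1,
                              roi = "OFC"))
  rec3 <- new("Recording", data = rbind(rec@data, rnorm(1000)),
              samplingRate = 1000, channelInfo = ci3,
              events = rec@events, processing = character())
  expect_warning(bipolarReference(rec3), "single contact")
})

test_that("artifact detection flags spikes with padded context", {
  rec <- makeNoiseRecording(nCh = 1, seconds = 60, seed = 2)
  rec@data[1, 30000] <- 50
  mask <- detectArtifacts(rec)
  expect_true(all(mask@mask[1, 29000:31000]))
  expect_lt(mean(mask@mask[1, ]), 0.2)
})

test_that("flag rate on clean background noise is small", {
  # smooth (1/f) background: amplitude and gradient nearly independent, so
  # the conjunction rule almost never fires and padding stays rare
  rec <- makeNoiseRecording(nCh = 1, seconds = 60, seed = 3)
  set.seed(31)
  rec@data[1, ] <- extinctRSA:::.coloredNoise(ncol(rec@data), 1, 1000)
  mask <- detectArtifacts(rec)
  expect_lt(mean(mask@mask), 0.02)
  # white noise: the sample-to-sample gradient is anticorrelated with
  # amplitude, so a handful of conjunction cores (each padded +/-1 s) is
  # expected; the rate must still stay below a few padded cores per minute
  recW <- makeNoiseRecording(nCh = 1, seconds = 60, seed = 3)
  maskW <- detectArtifacts(recW)
  expect_lt(mean(maskW@mask), 0.08)
})

test_that("zero-variance channels raise a named error", {
  rec <- makeNoiseRecording(nCh = 2, seconds = 5, seed = 4)
  rec@data[2, ] <- 7
  expect_error(detectArtifacts(rec), "AMY2")
})

test_that("detector is translation-equivariant", {
  rec <- makeNoiseRecording(nCh = 1, seconds = 30, seed = 5)
  rec@data[1, 10000] <- 60
  k <- 500
  shifted <- rec
  shifted@data <- cbind(rec@data[, (k + 1):ncol(rec@data), drop = FALSE],
                        rec@data[, 1:k, drop = FALSE])
  m1 <- detectArtifacts(rec)
  m2 <- detectArtifacts(shifted)
  core1 <- which(m1@mask[1, ])
  core2 <- which(m2@mask[1, ])
  # the spike neighbourhood moves back by k samples
  expect_true(all((10000 - k) %in% core2))
  expect_equal(length(core1), length(core2), tolerance = 0.02)
})

test_that("padding surrounds every flagged core as specified", {
  rec <- makeNoiseRecording(nCh = 1, seconds = 30, seed = 6)
  rec@data[1, c(5000, 20000)] <- 80
  mask <- detectArtifacts(rec)
  runs <- rle(as.vector(mask@mask[1, ]))
  lens <- runs$lengths[runs$values]
  expect_true(all(lens >= 2000))
})

test_that("epoching rejects exactly the artifact-hit trials", {
  sched <- makeToySchedule(n = 12)
  events <- makeToyEvents(sched)
  rec <- makeNoiseRecording(nCh = 2, seconds = 100, seed = 7,
                            events = events)
  emptyMask <- new("ArtifactMask",
                   mask = matrix(FALSE, 2, ncol(rec@data)),
                   thresholds = c(any = 6), padSeconds = 1,
                   samplingRate = 1000)
  ep0 <- epochRecording(rec, sched, emptyMask, minTrials = 2)
  expect_equal(nrow(ep0@rejected), 0)
  expect_equal(dim(ep0@data), c(12, 2, 7001))
  expect_equal(range(ep0@times), c(-3, 4))

  hit <- c(2, 5, 6, 9, 11)
  mask <- emptyMask
  for (tr in hit) {
    cue <- events$sample[events$marker == "cue" & events$trial == tr]
    mask@mask[1, cue + 100] <- TRUE
  }
  ep <- epochRecording(rec, sched, mask, minTrials = 2)
  expect_equal(sort(ep@rejected$trial), hit)
  expect_equal(nrow(ep@trialInfo), 12 - length(hit))

  # rejection monotonicity: more flags never fewer rejections
  mask2 <- mask
  mask2@mask[2, events$sample[events$marker == "cue" & events$trial == 3]] <-
    TRUE
  ep2 <- epochRecording(rec, sched, mask2, minTrials = 2)
  expect_gte(nrow(ep2@rejected), nrow(ep@rejected))
})

test_that("low-trial conditions are flagged excluded", {
  sched <- makeToySchedule(n = 12)
  events <- makeToyEvents(sched)
  rec <- makeNoiseRecording(nCh = 1, seconds = 100, seed = 8,
                            events = events)
  ep <- epochRecording(rec, sched, minTrials = 8)
  # each valence class has <= 8 of 12 trials here
  expect_true(any(ep@excluded))

  badSched <- makeToySchedule(n = 11)
  expect_error(epochRecording(rec, badSched), "disagrees")
})
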