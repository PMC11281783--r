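# Event detection: onsets, offsets, bouts, mismatch gating, trial state,
# binarization, random triggers.

test_that("locomotion onset follows the threshold/hold/quiet rule exactly", {
  fr <- 15
  expect_equal(nrow(detectLocomotionOnsets(rep(0, 300), fr)), 0L)
  # 2 s quiet then 2 s running: onset at the first above-threshold frame
  v <- c(rep(0, 30), rep(1, 30))
  on <- detectLocomotionOnsets(v, fr, edgeWindow = NULL)
  expect_equal(on$frame, 31L)
  expect_equal(on$time_s, 30 / fr)
  # running from frame 1: no 1-s quiet prelude, no onset
  expect_equal(nrow(detectLocomotionOnsets(rep(1, 300), fr,
                                           edgeWindow = NULL)), 0L)
})

test_that("locomotion offset mirrors the onset rule", {
  fr <- 15
  v <- c(rep(1, 30), rep(0, 30))
  off <- detectLocomotionOffsets(v, fr, edgeWindow = NULL)
  expect_equal(off$frame, 31L)
  expect_equal(nrow(detectLocomotionOffsets(rep(1, 300), fr,
                                            edgeWindow = NULL)), 0L)
  # a 0.5-s dip below threshold does not qualify as an offset
  v2 <- c(rep(1, 45), rep(0, 7), rep(1, 45))
  expect_equal(nrow(detectLocomotionOffsets(v2, fr, edgeWindow = NULL)), 0L)
})

test_that("detectors agree exactly with the brute-force scanner", {
  fr <- 15
  set.seed(11)
  for (rep in 1:200) {
    v <- randomVelocity(300)
    on <- detectLocomotionOnsets(v, fr, edgeWindow = NULL)$frame
    off <- detectLocomotionOffsets(v, fr, edgeWindow = NULL)$frame
    expect_identical(on, bruteOnsets(v, 0.25, 15L, 15L))
    expect_identical(off, bruteOffsets(v, 0.25, 15L, 15L))
    # with edge-window exclusion
    onE <- detectLocomotionOnsets(v, fr)$frame
    expect_identical(onE, bruteOnsets(v, 0.25, 15L, 15L, -30L, 45L))
  }
})

test_that("onsets and offsets alternate and shift equivariantly", {
  fr <- 15
  set.seed(12)
  for (rep in 1:50) {
    v <- randomVelocity(400)
    on <- detectLocomotionOnsets(v, fr, edgeWindow = NULL)$frame
    off <- detectLocomotionOffsets(v, fr, edgeWindow = NULL)$frame
    ev <- rbind(data.frame(f = on, t = rep("on", length(on))),
                data.frame(f = off, t = rep("off", length(off))))
    ev <- ev[order(ev$f), ]
    if (nrow(ev) > 1L)
      expect_true(all(ev$t[-1] != ev$t[-nrow(ev)]))
    # shifting the trace by k frames shifts every event by k
    k <- 25L
    v2 <- c(rep(0, k), v)
    on2 <- detectLocomotionOnsets(v2, fr, edgeWindow = NULL)$frame
    keep <- on2 > k   # events inside the appended quiet prefix may differ
    expect_true(all((on + k) %in% on2))
  }
})

test_that("bout segmentation pairs onsets with offsets and enforces separation", {
  fr <- 15
  on <- data.frame(event_type = "locomotion_onset",
                                            frame = 151L, time_s = 10,
                                            condition = NA, state = NA,
                                            orientation = NA, duration = NA)
  off <- data.frame(event_type = "locomotion_offset", frame = 301L,
                    time_s = 20, condition = NA, state = NA,
                    orientation = NA, duration = NA)
  b <- segmentBouts(on, off, fr)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_s, 10)
  # 2-s bout is discarded (below the 4-s separation)
  off2 <- off; off2$frame <- 181L
  expect_equal(nrow(segmentBouts(on, off2, fr)), 0L)
  # offsets before the first onset are skipped with a message
  off3 <- rbind(data.frame(event_type = "locomotion_offset", frame = 10L,
                           time_s = 10 / fr, condition = NA, state = NA,
                           orientation = NA, duration = NA), off)
  expect_message(b3 <- segmentBouts(on, off3, fr), "skipping")
  expect_equal(nrow(b3), 1L)
})

test_that("square-wave velocity yields one bout per high phase", {
  fr <- 15
  v <- rep(c(rep(0, 90), rep(1, 120)), 8)
  on <- detectLocomotionOnsets(v, fr, edgeWindow = NULL)
  off <- detectLocomotionOffsets(v, fr, edgeWindow = NULL)
  b <- segmentBouts(on, off, fr)
  expect_equal(nrow(b), 7L)   # the final high phase has no following offset
  expect_equal(unique(b$duration_s), 8)
})

test_that("mismatch gating keeps only uninterrupted-locomotion events", {
  fr <- 15
  mkEv <- function(frames) data.frame(event_type = "mismatch",
                                      frame = frames,
                                      time_s = (frames - 1) / fr,
                                      condition = "closed_loop", state = NA,
                                      orientation = NA, duration = 1)
  v <- rep(1, 600)
  expect_equal(nrow(filterMismatchEvents(mkEv(c(100L, 300L)), v, fr)), 2L)
  # a single sub-threshold frame at +0.4 s drops the event
  v2 <- v; v2[300L + 6L] <- 0.1
  kept <- filterMismatchEvents(mkEv(c(100L, 300L)), v2, fr)
  expect_equal(kept$frame, 100L)
  # random velocity: equality with a brute-force frame scan
  set.seed(13)
  for (rep in 1:50) {
    v3 <- randomVelocity(600)
    ev <- mkEv(seq(30L, 560L, by = 40L))
    got <- filterMismatchEvents(ev, v3, fr)$frame
    want <- ev$frame[vapply(ev$frame, function(f) {
      idx <- (f - 8L):(f + 14L)
      all(idx >= 1L) && all(idx <= 600L) && all(v3[idx] >= 0.25)
    }, logical(1))]
    expect_identical(got, want)
  }
})

test_that("trial state is locomotion only for fully supra-threshold windows", {
  fr <- 15
  v <- rep(1, 300); v[150] <- 0.1
  expect_equal(classifyTrialState(c(50L, 145L), v, fr),
               c("locomotion", "stationary"))
  expect_equal(classifyTrialState(100L, rep(0, 300), fr), "stationary")
})

test_that("binarization thresholds at exactly 0.25 cm/s", {
  expect_equal(binarizeVelocity(rep(0, 10)), rep(0, 10))
  expect_equal(binarizeVelocity(rep(1, 10)), rep(1, 10))
  ramp <- seq(0, 0.5, length.out = 101)
  b <- binarizeVelocity(ramp)
  expect_equal(min(which(b == 1)), min(which(ramp >= 0.25)))
})

test_that("random triggers are reproducible and drawn from locomotion frames", {
  fr <- 15
  v <- c(rep(0, 300), rep(1, 300), rep(0, 100))
  t1 <- drawRandomTriggers(v, 20L, fr, seed = 3L)
  t2 <- drawRandomTriggers(v, 20L, fr, seed = 3L)
  expect_identical(t1, t2)
  expect_true(all(v[t1$frame] >= 0.25))
  expect_error(drawRandomTriggers(rep(0, 300), 5L, fr), "no locomotion")
  expect_error(drawRandomTriggers(v, 1e6L, fr), "available")
})
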