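# Synthetic-session generator: determinism, behavior statistics, schedule
# structure, coding models, raw-fluorescence forward model.

test_that("identical config and seed give bit-identical sessions", {
  cfg <- tinyConfig()
  s1 <- simulateSession(cfg)
  s2 <- simulateSession(cfg)
  expect_identical(dff(s1), dff(s2))
  expect_identical(velocity(s1), velocity(s2))
  expect_identical(sessionEvents(s1), sessionEvents(s2))
  s3 <- simulateSession(tinyConfig(seed = 8L))
  expect_false(identical(dff(s1), dff(s3)))
})

test_that("zero bout rate gives a still mouse and an empty bout table", {
  beh <- generateBehavior(tinyConfig(boutRate = 0))
  expect_equal(nrow(beh$bouts), 0L)
  expect_true(all(beh$behavior$velocity < 0.2))
})

test_that("within-bout velocity declines by the configured fraction", {
  cfg <- synthConfig(seed = 7L, conditionDurations = c(dark = 32000),
                     boutRate = 0.5)
  beh <- generateBehavior(cfg)
  b <- beh$bouts
  v <- beh$behavior$velocity
  expect_gt(nrow(b), 200L)
  ratio <- mapply(function(on, off)
    mean(v[seq(off - 14L, off)]) / mean(v[seq(on, on + 14L)]),
    b$onset, b$offset)
  expect_lt(abs(mean(ratio) - (1 - cfg$velocityDecay)), 0.05)
})

test_that("velocity respects the in/out-of-bout separation bounds", {
  beh <- generateBehavior(tinyConfig())
  v <- beh$behavior$velocity
  b <- beh$bouts
  inBout <- rep(FALSE, length(v))
  for (i in seq_len(nrow(b))) inBout[b$onset[i]:b$offset[i]] <- TRUE
  expect_true(all(v[!inBout] < 0.2))
  expect_true(all(v >= 0))
  for (i in seq_len(nrow(b))) {
    inner <- v[b$onset[i]:b$offset[i]]
    expect_lte(sum(inner < 0.3), 2L)
  }
  # threshold-detected state agrees with ground-truth bout frames
  expect_gte(mean((v >= 0.25) == inBout), 0.98)
})

test_that("schedule tiles the session and stimuli respect the printed ranges", {
  cfg <- tinyConfig(conditionDurations = c(closed_loop = 120, grating = 120,
                                           open_loop = 60, dark = 60))
  sch <- generateSchedule(cfg)
  seg <- sch$schedule
  expect_equal(seg$start_frame[1], 1L)
  expect_equal(seg$start_frame[-1], head(seg$end_frame, -1) + 1L)
  expect_equal(seg$end_frame[nrow(seg)], 360L * 15L)
  ev <- sch$events
  gr <- ev[ev$event_type == "grating_onset", ]
  expect_gt(nrow(gr), 5L)
  expect_true(all(gr$duration >= 2 & gr$duration <= 3))
  isi <- diff(gr$time_s) - head(gr$duration, -1)
  expect_true(all(isi >= 2 - 1e-9 & isi <= 4 + 1e-9))
  expect_true(all(gr$orientation %in%
                    c(0, 45, 90, 270, (c(0, 45, 90, 270) + 180) %% 360)))
  mm <- ev[ev$event_type == "mismatch", ]
  cl <- seg[seg$condition == "closed_loop", ]
  inClosed <- vapply(mm$frame, function(f)
    any(f >= cl$start_frame & f <= cl$end_frame), logical(1))
  expect_true(all(inClosed))
})

test_that("a grating segment shorter than one stimulus cycle errors", {
  expect_error(generateSchedule(tinyConfig(
    conditionDurations = c(grating = 5, dark = 60))), "stimulus cycle")
})

test_that("noiseless binary-state unit with delta kernel tracks the state", {
  cfg <- tinyConfig(unitsPerSite = 2L, sitesPerMouse = 1L,
                    codingModels = c(binary_state = 1), noiseSd = 0,
                    stateLag = 0, kernelRise = 0, kernelDecay = 0,
                    amplitudeJitterSd = 0, boutGainSd = 0)
  s <- simulateSession(cfg)
  expect_equal(unname(dff(s)[1, ]),
               cfg$amplitude * binarizeVelocity(velocity(s)),
               tolerance = 1e-12)
})

test_that("multiplicative locomotion gain doubles the grating response", {
  # a fast kernel keeps one trial's response from bleeding into the next
  # trial's baseline, so the trial-gain ratio is exact by construction
  cfg <- tinyConfig(unitsPerSite = 4L, sitesPerMouse = 1L,
                    conditionDurations = c(closed_loop = 200, grating = 400),
                    codingModels = c(visual = 1), noiseSd = 0,
                    responseGainMult = 1, responseGainAdd = 0,
                    tuningKappa = 0, layer5Shortening = 0L,
                    kernelRise = 0.05, kernelDecay = 0.3,
                    amplitudeJitterSd = 0, boutGainSd = 0)
  s <- simulateSession(cfg)
  ev <- sessionEvents(s)
  gr <- ev[ev$event_type == "grating_onset", ]
  st <- classifyTrialState(gr$frame, velocity(s), frameRate(s))
  expect_true(all(c("locomotion", "stationary") %in% st))
  eta <- eventTriggeredMatrix(s, gr$frame, baseline = c(-0.5, 0),
                              response = c(0.5, 2))
  d <- eta@responseMeans - eta@baselineMeans
  rLoco <- mean(d[1, st == "locomotion"])
  rStat <- mean(d[1, st == "stationary"])
  expect_equal(rLoco / rStat, 2, tolerance = 0.1)
})

test_that("state-dependent factor loadings set per-state pairwise correlations", {
  cfg <- synthConfig(nMice = 1L, sitesPerMouse = 1L, unitsPerSite = 40L,
                     conditionDurations = c(closed_loop = 400, dark = 400),
                     codingModels = c(silent = 1),
                     sharedNoiseLoadingStationary = sqrt(0.8),
                     sharedNoiseLoadingLocomotion = sqrt(0.2),
                     seed = 15L)
  s <- simulateSession(cfg)
  v <- velocity(s)
  M <- dff(s)
  rIn <- function(mask) {
    C <- cor(t(M[, mask]))
    mean(C[upper.tri(C)])
  }
  rStat <- rIn(v < 0.25)
  rLoco <- rIn(v >= 0.25)
  expect_gt(rStat, rLoco)
  gt <- groundTruth(s)$corr_targets
  expect_lt(abs(rStat - gt$r_stationary[1]), 0.05)
  expect_lt(abs(rLoco - gt$r_locomotion[1]), 0.05)
})

test_that("raw-fluorescence forward model is consistent and validated", {
  cfg <- tinyConfig(unitsPerSite = 2L, sitesPerMouse = 1L, noiseSd = 0,
                    bleachTau = Inf, F0 = 100, F0JitterSd = 0, rawOffset = 0,
                    boutRate = 1, boutDurationMeanLog = log(9),
                    boutDurationMax = 15)
  s <- simulateSession(cfg, makeRaw = TRUE)
  expect_error(generateRawFluorescence(dff(s), tinyConfig(F0 = -1)), "F0")
  # no-drift round trip through the percentile filter
  rec <- computeDFF(rawF(s))
  core <- 600:(ncol(s) - 600)
  expect_lt(max(abs(rec[, core] - dff(s)[, core])), 1e-6)
  # additive offset compresses the dF/F scale by F0 / (F0 + offset)
  cfgOff <- tinyConfig(unitsPerSite = 2L, sitesPerMouse = 1L, noiseSd = 0,
                       bleachTau = Inf, F0 = 100, F0JitterSd = 0,
                       rawOffset = 25, boutRate = 1,
                       boutDurationMeanLog = log(9), boutDurationMax = 15)
  s2 <- simulateSession(cfgOff, makeRaw = TRUE)
  rec2 <- computeDFF(rawF(s2))
  sel <- which(abs(dff(s2)[1, ]) > 0.5)
  sel <- sel[sel > 600 & sel < ncol(s2) - 600]
  expect_equal(mean(rec2[1, sel] / dff(s2)[1, sel]), 100 / 125,
               tolerance = 1e-6)
})
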