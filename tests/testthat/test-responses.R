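# Event-triggered quantification.

fr <- 15

test_that("event-triggered response scalars recover a unit step", {
  n <- 3000
  events <- c(500L, 1200L, 2000L)
  tr <- matrix(0, 2, n)
  for (f in events) tr[, f:(f + 44L)] <- 1
  eta <- eventTriggeredMatrix(tr, events, fr)
  expect_equal(unname(responseScalars(eta)), c(1, 1))
  tAxis <- snippetTime(eta)
  base <- tAxis >= -1 & tAxis < -0.5
  expect_equal(max(abs(meanTrace(eta)[, base])), 0)
  # single event, ramp trace: mean trace equals the snippet
  ramp <- matrix(seq_len(n) / n, 1)
  eta1 <- eventTriggeredMatrix(ramp, 1000L, fr)
  snip <- eta1@snippets[1, 1, ]
  expect_equal(unname(meanTrace(eta1)[1, ]),
               snip - mean(snip[base]))
})

test_that("uncorrelated noise gives near-zero responses", {
  set.seed(21)
  n <- 20000
  tr <- matrix(rnorm(n, 0, 1), 1)
  events <- as.integer(seq(100, n - 100, length.out = 100))
  eta <- eventTriggeredMatrix(tr, events, fr)
  d <- eta@responseMeans[1, ] - eta@baselineMeans[1, ]
  expect_lt(abs(responseScalars(eta)[1]), 3 * sd(d) / sqrt(length(d)))
})

test_that("responses and latencies are invariant to constant offsets", {
  set.seed(22)
  n <- 5000
  tr <- matrix(rnorm(n, 0, 0.1), 1)
  events <- as.integer(seq(200, n - 200, length.out = 20))
  for (f in events) tr[, f:(f + 30L)] <- tr[, f:(f + 30L)] + 1
  eta1 <- eventTriggeredMatrix(tr, events, fr)
  eta2 <- eventTriggeredMatrix(tr + 7, events, fr)
  expect_equal(responseScalars(eta1), responseScalars(eta2))
  expect_equal(onsetLatency(eta1), onsetLatency(eta2))
})

test_that("responsiveness classification handles shifts, ties, and exclusion", {
  n <- 4000
  events <- as.integer(seq(200, n - 200, length.out = 10))
  tr <- matrix(0, 3, n)
  for (f in events) tr[1, f:(f + 30L)] <- 1    # constant positive shift
  # unit 2: flat; unit 3: same as 1 (will get < 5 onsets)
  tr[3, ] <- tr[1, ]
  eta <- eventTriggeredMatrix(tr, events, fr)
  eta@nOnsets[3] <- 4L
  flags <- classifyResponsive(eta)
  expect_true(flags[1])        # zero-variance nonzero shift: responsive
  expect_false(flags[2])       # identical zero differences: not responsive
  expect_true(is.na(flags[3])) # too few onsets: excluded, not FALSE
})

test_that("type-I error of the responsiveness test is near alpha", {
  set.seed(23)
  nU <- 1000
  n <- 3000
  events <- as.integer(seq(100, n - 100, length.out = 20))
  tr <- matrix(rnorm(nU * n), nU)
  flags <- classifyResponsive(eventTriggeredMatrix(tr, events, fr))
  expect_lt(abs(mean(flags) - 0.05), 0.02)
})

test_that("responsive fractions per site report the chance level", {
  flags <- c(TRUE, TRUE, FALSE, NA, TRUE, FALSE)
  sites <- c("a", "a", "a", "a", "b", "b")
  rf <- responsiveFractionBySite(flags, sites)
  expect_equal(unname(rf$fractions), c(2 / 3, 1 / 2))
  expect_equal(rf$chance, 0.05)
})

test_that("latency is the first sustained 2-SD crossing of the mean trace", {
  n <- 4000
  events <- as.integer(seq(200, n - 200, length.out = 8))
  tr <- matrix(rnorm(n, 0, 1e-3), 1)
  for (f in events) tr[1, (f + 8L):(f + 59L)] <- 1  # step at +0.533 s
  eta <- eventTriggeredMatrix(tr, events, fr)
  expect_equal(onsetLatency(eta)[1], 8 / fr, tolerance = 1e-9)
  # flat trace: undefined, with a warning about zero baseline SD
  flat <- matrix(0, 1, n)
  etaF <- eventTriggeredMatrix(flat, events, fr)
  expect_warning(latF <- onsetLatency(etaF), "baseline SD")
  expect_true(is.na(latF[1]))
})

test_that("grating latency enforces its hold within the search window", {
  n <- 4000
  events <- as.integer(seq(200, n - 200, length.out = 8))
  mk <- function(stepAt, len) {
    tr <- matrix(rnorm(n, 0, 1e-3), 1)
    for (f in events) tr[1, (f + stepAt):(f + stepAt + len)] <- 1
    eventTriggeredMatrix(tr, events, fr, window = c(-1, 2.5),
                         baseline = c(-0.5, 0), response = c(0.5, 2))
  }
  expect_equal(gratingLatency(mk(3L, 40L))[1], 3 / fr, tolerance = 1e-9)
  # crossing at +1.9 s leaves less than the 1/3-s hold: excluded
  expect_true(is.na(gratingLatency(mk(29L, 60L))[1]))
})

test_that("velocity tuning reproduces step and linear activity profiles", {
  set.seed(24)
  v <- c(abs(rnorm(3000, 0, 0.1)), runif(5000, 0.3, 6.2))
  sites <- rep(c("a", "b"), each = 10)
  actStep <- matrix(rep(binarizeVelocity(v), 20), 20, byrow = TRUE)
  tc <- velocityTuningCurve(actStep, v, sites, nBoot = 200L, seed = 1L)
  below <- which(tc$bin_hi <= 0.25 & tc$n_frames > 0)
  above <- which(tc$bin_lo >= 0.3 & tc$n_frames > 0)
  expect_true(all(tc$median[below] < 0.05))
  expect_true(all(tc$median[above] > 0.95))
  actLin <- matrix(rep(v, 20), 20, byrow = TRUE)
  tcL <- velocityTuningCurve(actLin, v, sites, nBoot = 200L, seed = 1L)
  ok <- tcL$n_frames > 50
  expect_lt(max(abs(tcL$median[ok] - tcL$bin_mid[ok])), 0.1)
  # bins without frames are undefined, not zero
  vLow <- runif(2000, 0, 1)
  tcE <- velocityTuningCurve(matrix(vLow, 1), vLow, "a", nBoot = 50L,
                             seed = 1L)
  expect_true(all(is.na(tcE$median[tcE$n_frames == 0L])))
  expect_gt(sum(tcE$n_frames == 0L), 0L)
})

test_that("binarization comparison separates the two coding models", {
  set.seed(25)
  v <- c(runif(2000, 0, 0.2), runif(2000, 0.3, 6)) [sample(4000)]
  b <- binarizeVelocity(v)
  tr <- rbind(b + rnorm(4000, 0, 0.01),
              v + rnorm(4000, 0, 0.01),
              rnorm(4000))
  bc <- binarizationComparison(tr, v)
  expect_gt(bc$r_binary[1], bc$r_velocity[1])
  expect_gt(bc$r_velocity[2], bc$r_binary[2])
  expect_lt(max(abs(bc[3, c("r_velocity", "r_binary")])), 0.05)
  # no locomotion: binary regressor has zero variance
  bc0 <- binarizationComparison(tr[, 1:2000], v[1:2000] * 0)
  expect_true(all(is.na(bc0$r_binary)))
})

test_that("bout onset/offset correlations behave at the construction limits", {
  n <- 20000
  set.seed(26)
  onsets <- as.integer(seq(200, n - 400, by = 400))
  bouts <- data.frame(onset = onsets, offset = onsets + 150L,
                      duration_s = 10)
  # population activity with per-bout amplitude held across the bout
  amp <- runif(length(onsets), 0.5, 2)
  tr <- matrix(0, 1, n)
  v <- rep(0.01, n)
  for (i in seq_along(onsets)) {
    idx <- onsets[i]:(onsets[i] + 150L)
    tr[1, idx] <- amp[i]
    v[idx] <- amp[i]
  }
  bc <- boutResponseCorrelation(tr, v, bouts, fr)
  expect_equal(bc$r_activity, 1, tolerance = 1e-9)
  expect_equal(bc$r_velocity, 1, tolerance = 1e-9)
  # unstructured traces fall well below the per-bout-stable case (the
  # shared baseline window keeps a positive floor under independence)
  tr2 <- matrix(rnorm(n), 1)
  bc2 <- boutResponseCorrelation(tr2, v, bouts, fr)
  expect_lt(bc2$r_activity, 0.9)
  expect_error(boutResponseCorrelation(tr, v, bouts[1:2, ], fr), "bouts")
})

test_that("split-half selection never reuses reporting trials", {
  set.seed(27)
  n <- 8000
  events <- as.integer(seq(100, n - 100, length.out = 40))
  nU <- 50
  tr <- matrix(rnorm(nU * n, 0, 0.3), nU)
  planted <- 1:5
  for (f in events) tr[planted, f:(f + 20L)] <- tr[planted, f:(f + 20L)] + 3
  eta <- eventTriggeredMatrix(tr, events, fr, baseline = c(-0.5, 0),
                              response = c(0.5, 2))
  sel <- splitHalfTopResponders(eta, 0.10, seed = 5L)
  expect_length(intersect(sel$selectionTrials, sel$heldOutTrials), 0L)
  expect_equal(sort(c(sel$selectionTrials, sel$heldOutTrials)),
               seq_along(events))
  expect_length(sel$selected, 5L)
  expect_gte(length(intersect(sel$selected, planted)), 5L * 0.9)
})

test_that("gain decomposition recovers multiplicative and additive changes", {
  oris <- rep(c(0, 45, 90, 135, 180, 225, 270, 315), times = 12)
  nTrial <- length(oris)
  cond <- rep(c("stationary", "double", "shifted"), each = nTrial / 3)
  set.seed(28)
  tuning <- function(o, p) exp(2 * (cos(2 * pi / 180 * (o - p)) - 1))
  nU <- 12
  pref <- sample(c(0, 45, 90, 135), nU, replace = TRUE)
  resp <- t(vapply(seq_len(nU), function(i) {
    base <- tuning(oris, pref[i])
    base * ifelse(cond == "double", 2, 1) +
      ifelse(cond == "shifted", 0.5, 0)
  }, numeric(nTrial)))
  g <- orientationGainDecomposition(resp, oris, cond, seed = 2L)
  gd <- g$gains[g$gains$condition == "double", ]
  gs <- g$gains[g$gains$condition == "shifted", ]
  expect_equal(gd$slope, 2, tolerance = 0.05)
  expect_equal(gd$intercept, 0, tolerance = 0.05)
  expect_equal(gs$slope, 1, tolerance = 0.05)
  expect_equal(gs$intercept, 0.5, tolerance = 0.05)
  expect_error(orientationGainDecomposition(resp[, oris == 0],
                                            oris[oris == 0],
                                            cond[oris == 0]),
               "orientations")
})

test_that("condition-wise correlations respect masks and the pupil rule", {
  n <- 6000
  cond <- rep(c("closed_loop", "dark"), each = n / 2)
  act <- rnorm(n)
  r <- conditionBehaviorCorrelation(act, act, cond, frameRate = fr)
  expect_equal(unname(r), c(1, 1))
  # a condition with under 30 s of valid pupil data is excluded
  valid <- rep(TRUE, n); valid[cond == "dark"][-(1:300)] <- FALSE
  rp <- conditionBehaviorCorrelation(act, act, cond, valid, fr,
                                     isPupil = TRUE)
  expect_equal(unname(rp["closed_loop"]), 1)
  expect_true(is.na(rp["dark"]))
})

test_that("pupil-locomotion coupling is recovered as weaker in darkness", {
  s <- simulateSession(tinyConfig(seed = 31L, unitsPerSite = 4L))
  rp <- conditionBehaviorCorrelation(velocity(s),
                                     behaviorChannel(s, "pupil"),
                                     behaviorChannel(s, "condition"),
                                     behaviorChannel(s, "valid"), fr,
                                     isPupil = TRUE)
  expect_lt(rp["dark"], min(rp[c("closed_loop", "open_loop", "grating")]))
})

test_that("random-trigger null band is centred, seeded, and n-dependent", {
  set.seed(29)
  n <- 9000
  v <- rep(c(rep(0, 300), rep(1, 300)), 15)
  tr <- matrix(rnorm(2 * n, 0, 0.5), 2)
  b1 <- randomTriggerNullBand(tr, v, fr, nDraws = 200L, seed = 4L)
  b2 <- randomTriggerNullBand(tr, v, fr, nDraws = 200L, seed = 4L)
  expect_identical(b1, b2)
  # constant trace: zero-width band at zero
  bc <- randomTriggerNullBand(matrix(1, 1, n), v, fr, nDraws = 50L,
                              seed = 4L)
  expect_equal(max(abs(c(bc$lower, bc$upper))), 0)
  # fewer draws widen the confidence band
  b3 <- randomTriggerNullBand(tr, v, fr, nDraws = 20L, seed = 4L)
  expect_gt(mean(b3$upper - b3$lower), mean(b1$upper - b1$lower))
})
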