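#' Configuration for the synthetic-session generator
#'
#' Builds a validated configuration list for [simulateSession()] and the
#' individual generator stages. The generator emulates the statistical
#' structure the downstream analyses assume: nested mouse -> site -> unit
#' organisation; bout-structured locomotion whose velocity declines within a
#' bout; "cholinergic-axon-like" units whose drive is a lagged binary
#' function of locomotion state convolved with a slow calcium kernel;
#' visually tuned neurons with additive and multiplicative locomotion gain
#' and a shortened layer-5-like response latency during locomotion; a
#' shared latent factor per site whose loading is locomotion-state dependent
#' (so pairwise correlations change with state); pupil coupled to locomotion
#' with condition-dependent strength; and raw fluorescence with slow bleach.
#'
#' @param nMice,sitesPerMouse,unitsPerSite cohort shape.
#' @param frameRate sampling rate in Hz (canonical 15).
#' @param conditionDurations named numeric vector of segment durations in
#'   seconds; names from `closed_loop`, `open_loop`, `grating`, `dark` (a
#'   name may repeat). Order defines the session schedule.
#' @param boutRate locomotion bouts per minute (0 = no locomotion).
#' @param boutDurationMeanLog,boutDurationSdLog log-normal bout-duration
#'   parameters (seconds); durations are clipped to
#'   `[boutDurationMin, boutDurationMax]`.
#' @param boutDurationMin,boutDurationMax bout duration clip range (s).
#' @param durationPeakCoupling log-scale regression of bout duration on
#'   bout peak velocity (fast runs tend to be sustained runs): the
#'   duration meanlog is shifted by `coupling * (log(peak) -
#'   peakVelocityMeanLog)`.
#' @param boutGapMin minimal stationary gap between bouts (s).
#' @param peakVelocityMeanLog,peakVelocitySdLog log-normal peak-velocity
#'   parameters (cm/s), clipped to `peakVelocityRange`.
#' @param peakVelocityRange clip range for bout peak velocity (cm/s).
#' @param velocityDecay mean fractional within-bout velocity decline: the
#'   mean velocity over the last second of a bout is, in expectation,
#'   `(1 - velocityDecay)` times the mean over the first second (before
#'   noise).
#' @param velocityDecaySdLog per-bout log-normal spread of the decline
#'   multiplier `1 - decay` (bout profiles are idiosyncratic: some bouts
#'   slow down sharply, some hold or even gain speed); the per-bout
#'   multiplier is `(1 - velocityDecay) * exp(s*z - s^2/2)` clipped to
#'   `[0.1, 1.3]`, so its expectation stays `1 - velocityDecay`.
#' @param boutGainSd SD of the per-bout log-normal population response
#'   gain applied to the locomotion drive of `binary_state` and
#'   `linear_velocity` units (arousal-like bout-to-bout variability,
#'   shared across units).
#' @param velocityNoiseSd within-bout velocity noise SD, relative to peak.
#' @param velocityNoiseTau smoothing time constant of that noise (s).
#' @param stationaryJitter SD of the non-negative stationary velocity
#'   jitter (cm/s); clipped below 0.19 cm/s.
#' @param codingModels named non-negative weights over unit coding models
#'   `binary_state`, `linear_velocity`, `visual`, `mismatch`, `silent`;
#'   units per site are allocated proportionally.
#' @param stateLag lag (s) between locomotion state and unit drive
#'   (default 0.477 s, the observed mean onset lag of cholinergic axons).
#' @param kernelRise,kernelDecay calcium-kernel time constants (s);
#'   `kernelDecay = 0` requests a delta kernel.
#' @param amplitude mean unit response amplitude (dF/F units).
#' @param amplitudeJitterSd SD of the per-unit log-normal amplitude jitter.
#' @param responseGainAdd,responseGainMult additive / multiplicative
#'   locomotion gain of visual responses: a locomotion-trial response is
#'   `(1 + mult) * stationary + add`.
#' @param visualLatency baseline latency of visual responses (s).
#' @param layer5Shortening latency shortening (frames) of layer-5-like
#'   visual units during locomotion.
#' @param layerL5Fraction fraction of visual units labeled layer 5.
#' @param tuningKappa von-Mises orientation-tuning concentration.
#' @param sharedNoiseLoadingStationary,sharedNoiseLoadingLocomotion shared
#'   latent-factor loadings in `[0, 1]` by locomotion state; vectors define
#'   several unit groups, each with its own factor. The within-group mean
#'   pairwise correlation target in a state is `loading^2`.
#' @param noiseSd unit noise SD (dF/F units); SNR is `amplitude / noiseSd`.
#' @param noiseAr AR(1) coefficient of the slow noise component at 15 Hz.
#' @param mismatchRatePerMin rate of 1-s visual-flow halts in closed loop.
#' @param optoRatePerMin rate of optogenetic stimulation events (0 = none).
#' @param optoDuration duration of each opto event (s).
#' @param pupilCoupling named per-condition coupling of pupil to the
#'   low-pass filtered locomotion state.
#' @param pupilLuminance named per-condition pupil baseline (luminance
#'   term; larger in darkness where the pupil dilates).
#' @param pupilTau pupil low-pass time constant (s).
#' @param pupilNoiseSd pupil measurement noise SD.
#' @param blinkRate fraction of frames marked invalid (blinks).
#' @param bleachTau fluorescence bleaching time constant (s).
#' @param F0 baseline fluorescence (a.u.); must be positive.
#' @param F0JitterSd per-unit log-normal jitter of F0.
#' @param rawOffset additive raw-fluorescence offset (a.u.).
#' @param seed root RNG seed; all stages draw from named substreams of it.
#'
#' @return a validated list of class `"SynthConfig"`.
#' @export
synthConfig <- function(nMice = 2L, sitesPerMouse = 2L, unitsPerSite = 20L,
                        frameRate = 15,
                        conditionDurations = c(closed_loop = 300,
                                               open_loop = 300,
                                               grating = 300, dark = 300),
                        boutRate = 0.5,
                        boutDurationMeanLog = log(40),
                        boutDurationSdLog = 0.6,
                        boutDurationMin = 5, boutDurationMax = 120,
                        durationPeakCoupling = 0.8,
                        boutGapMin = 8,
                        peakVelocityMeanLog = log(2),
                        peakVelocitySdLog = 0.7,
                        velocityDecay = 0.4, velocityDecaySdLog = 0.8,
                        peakVelocityRange = c(0.7, 6),
                        velocityNoiseSd = 0.3, velocityNoiseTau = 1,
                        boutGainSd = 0.4,
                        stationaryJitter = 0.02,
                        codingModels = c(binary_state = 1),
                        stateLag = 0.477,
                        kernelRise = 0.2, kernelDecay = 1.5,
                        amplitude = 1, amplitudeJitterSd = 0.2,
                        responseGainAdd = 0, responseGainMult = 1,
                        visualLatency = 0.2, layer5Shortening = 2L,
                        layerL5Fraction = 0.5,
                        tuningKappa = 2,
                        sharedNoiseLoadingStationary = 0.3,
                        sharedNoiseLoadingLocomotion = 0.3,
                        noiseSd = 0.5, noiseAr = 0.5,
                        mismatchRatePerMin = 2,
                        optoRatePerMin = 0, optoDuration = 1,
                        pupilCoupling = c(closed_loop = 0.8, open_loop = 0.8,
                                          grating = 0.8, dark = 0.4),
                        pupilLuminance = c(closed_loop = 0.5, open_loop = 0.5,
                                           grating = 0.4, dark = 0.8),
                        pupilTau = 2, pupilNoiseSd = 0.05,
                        blinkRate = 0.002,
                        bleachTau = Inf, F0 = 100, F0JitterSd = 0.1,
                        rawOffset = 0,
                        seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "SynthConfig"
  validateSynthConfig(cfg)
  cfg
}

validateSynthConfig <- function(cfg) {
  if (cfg$frameRate <= 0) stop("frameRate must be positive")
  if (any(cfg$conditionDurations <= 0))
    stop("condition durations must be positive")
  if (is.null(names(cfg$conditionDurations)) ||
      !all(names(cfg$conditionDurations) %in%
           c("closed_loop", "open_loop", "grating", "dark")))
    stop("conditionDurations must be named with known condition labels")
  loadings <- c(cfg$sharedNoiseLoadingStationary,
                cfg$sharedNoiseLoadingLocomotion)
  if (any(loadings < 0 | loadings > 1))
    stop("shared-noise loadings must lie in [0, 1]")
  if (length(cfg$sharedNoiseLoadingStationary) !=
      length(cfg$sharedNoiseLoadingLocomotion))
    stop("stationary and locomotion loading vectors must have equal length")
  known <- c("binary_state", "linear_velocity", "visual", "mismatch",
             "silent")
  if (is.null(names(cfg$codingModels)) ||
      !all(names(cfg$codingModels) %in% known))
    stop("unknown coding model in codingModels; known models: ",
         paste(known, collapse = ", "))
  if (any(cfg$codingModels < 0) || sum(cfg$codingModels) <= 0)
    stop("codingModels weights must be non-negative with positive sum")
  if (cfg$boutRate < 0) stop("boutRate must be non-negative")
  if (cfg$velocityDecay < 0 || cfg$velocityDecay >= 1)
    stop("velocityDecay must lie in [0, 1)")
  if (cfg$F0 <= 0) stop("F0 must be positive")
  invisible(TRUE)
}

sessionFrames <- function(cfg) {
  sum(secToFrames(cfg$conditionDurations, cfg$frameRate))
}

#' Generate the condition schedule and stimulus events
#'
#' Tiles the session with the configured condition segments and places
#' stimulus events: full-field drifting gratings (duration uniform in
#' `[2, 3]` s, gray inter-stimulus intervals uniform in `[2, 4]` s,
#' orientations from 0/45/90/270 degrees in either drift direction) inside
#' grating segments, 1-s visual-flow halts (visuomotor mismatches) inside
#' closed-loop segments only, and optional optogenetic stimulation events.
#'
#' @param config a [synthConfig()].
#' @return list with `schedule` (data.frame: `condition`, `start_frame`,
#'   `end_frame`, inclusive 1-based bounds) and `events` (event table).
#' @export
generateSchedule <- function(config) {
  validateSynthConfig(config)
  fr <- config$frameRate
  durs <- config$conditionDurations
  nseg <- secToFrames(durs, fr)
  ends <- cumsum(nseg)
  starts <- c(1L, head(ends, -1) + 1L)
  sched <- data.frame(condition = names(durs), start_frame = starts,
                      end_frame = as.integer(ends),
                      stringsAsFactors = FALSE)
  if (any(sched$condition == "grating" & durs < 7))
    stop("grating segments must be at least one stimulus cycle (7 s) long")

  withSeed(subSeed(config$seed, "schedule"), {
    gratings <- NULL
    for (i in which(sched$condition == "grating")) {
      t <- sched$start_frame[i] / fr   # seconds
      segEnd <- sched$end_frame[i] / fr
      fs <- integer(0); oris <- numeric(0); dd <- numeric(0)
      repeat {
        t <- t + runif(1, 2, 4)            # gray ISI
        dur <- runif(1, 2, 3)
        if (t + dur > segEnd) break
        ori <- sample(c(0, 45, 90, 270), 1L)
        dir <- sample(c(0, 180), 1L)
        fs <- c(fs, secToFrames(t, fr) + 1L)
        oris <- c(oris, (ori + dir) %% 360)
        dd <- c(dd, dur)
        t <- t + dur
      }
      gratings <- bindEventTables(gratings,
        makeEventTable("grating_onset", fs, fr, condition = "grating",
                       orientation = oris, duration = dd))
    }
    mism <- NULL
    if (config$mismatchRatePerMin > 0) {
      for (i in which(sched$condition == "closed_loop")) {
        segDur <- (sched$end_frame[i] - sched$start_frame[i] + 1L) / fr
        nEv <- max(0L, round(config$mismatchRatePerMin * segDur / 60))
        if (nEv == 0L) next
        # spaced placement with >= 8 s gaps, >= 3 s from segment edges
        cand <- sort(runif(4L * nEv, 3, segDur - 4))
        keep <- numeric(0)
        for (tt in cand) {
          if (length(keep) == 0L || tt - tail(keep, 1) >= 8) keep <- c(keep, tt)
          if (length(keep) == nEv) break
        }
        mism <- bindEventTables(mism,
          makeEventTable("mismatch",
                         sched$start_frame[i] + secToFrames(keep, fr), fr,
                         condition = "closed_loop", duration = 1))
      }
    }
    opto <- NULL
    if (config$optoRatePerMin > 0) {
      totalDur <- sum(durs)
      nEv <- max(0L, round(config$optoRatePerMin * totalDur / 60))
      if (nEv > 0L) {
        gap <- config$optoDuration + 4
        cand <- sort(runif(4L * nEv, 3, totalDur - config$optoDuration - 3))
        keep <- numeric(0)
        for (tt in cand) {
          if (length(keep) == 0L || tt - tail(keep, 1) >= gap)
            keep <- c(keep, tt)
          if (length(keep) == nEv) break
        }
        fsO <- secToFrames(keep, fr) + 1L
        condO <- conditionOfFrames(fsO, sched)
        opto <- makeEventTable("opto_onset", fsO, fr, condition = condO,
                               duration = config$optoDuration)
      }
    }
    list(schedule = sched, events = bindEventTables(gratings, mism, opto))
  })
}

conditionOfFrames <- function(frames, sched) {
  out <- rep(NA_character_, length(frames))
  for (i in seq_len(nrow(sched))) {
    inSeg <- frames >= sched$start_frame[i] & frames <= sched$end_frame[i]
    out[inSeg] <- sched$condition[i]
  }
  out
}

#' Generate behavior channels and the ground-truth bout table
#'
#' Locomotion is a semi-Markov two-state process: stationary gaps alternate
#' with bouts of log-normal duration. Within a bout, velocity follows a
#' linear decline from its peak (so the mean over the last second is
#' `1 - velocityDecay` times the mean over the first second) plus smoothed
#' noise, clipped to at least 0.3 cm/s; outside bouts, velocity is a small
#' non-negative jitter below 0.2 cm/s. Visual flow equals velocity in closed
#' loop (zeroed during mismatch halts), is a replay of the closed-loop flow
#' in open loop, and is zero in dark and grating segments. Pupil diameter is
#' a low-pass filtered locomotion state scaled by a condition-dependent
#' coupling plus a condition-dependent luminance baseline and noise.
#'
#' @param config a [synthConfig()].
#' @param schedule optional result of [generateSchedule()]; generated from
#'   `config` when NULL.
#' @return list with `behavior` (data.frame: `velocity`, `flow`, `pupil`,
#'   `face`, `valid`, `condition`) and `bouts` (data.frame: `onset`,
#'   `offset` frames, inclusive; `duration_s`).
#' @export
generateBehavior <- function(config, schedule = NULL) {
  validateSynthConfig(config)
  if (is.null(schedule)) schedule <- generateSchedule(config)
  sched <- schedule$schedule
  events <- schedule$events
  fr <- config$frameRate
  n <- sessionFrames(config)

  withSeed(subSeed(config$seed, "behavior"), {
    v <- pmin(abs(rnorm(n, 0, config$stationaryJitter)), 0.19)
    onsets <- integer(0); offsets <- integer(0)
    if (config$boutRate > 0) {
      meanGap <- max(config$boutGapMin + 2,
                     60 / config$boutRate - exp(config$boutDurationMeanLog))
      t <- 5 + rexp(1, 1 / (meanGap - config$boutGapMin))
      while (TRUE) {
        peak <- min(config$peakVelocityRange[2],
                    max(config$peakVelocityRange[1],
                        rlnorm(1, config$peakVelocityMeanLog,
                               config$peakVelocitySdLog)))
        durMeanLog <- config$boutDurationMeanLog +
          config$durationPeakCoupling *
            (log(peak) - config$peakVelocityMeanLog)
        dur <- min(config$boutDurationMax,
                   max(config$boutDurationMin,
                       rlnorm(1, durMeanLog, config$boutDurationSdLog)))
        f0 <- secToFrames(t, fr) + 1L
        f1 <- f0 + secToFrames(dur, fr) - 1L
        if (f1 > n - secToFrames(5, fr)) break
        s2 <- config$velocityDecaySdLog
        mult <- min(1.3, max(0.1, (1 - config$velocityDecay) *
                               exp(s2 * rnorm(1) - s2^2 / 2)))
        decay <- 1 - mult
        nb <- f1 - f0 + 1L
        tt <- (seq_len(nb) - 1) / fr
        g <- pmin(1, pmax(0, (tt - 0.5) / max(dur - 1, 0.1)))
        base <- peak * (1 - decay * g)
        noise <- expSmooth(rnorm(nb, 0, config$velocityNoiseSd * peak),
                           config$velocityNoiseTau, fr)
        noise <- noise - mean(noise)
        v[f0:f1] <- pmax(base + noise, 0.3)
        onsets <- c(onsets, f0); offsets <- c(offsets, f1)
        t <- t + dur + config$boutGapMin +
          rexp(1, 1 / (meanGap - config$boutGapMin))
      }
    }
    bouts <- data.frame(onset = onsets, offset = offsets,
                        duration_s = (offsets - onsets + 1L) / fr)

    cond <- conditionOfFrames(seq_len(n), sched)
    flow <- numeric(n)
    closedIdx <- which(sched$condition == "closed_loop")
    for (i in closedIdx) {
      idx <- sched$start_frame[i]:sched$end_frame[i]
      flow[idx] <- v[idx]
    }
    if (!is.null(events) && nrow(events) > 0) {
      mm <- events[events$event_type == "mismatch", , drop = FALSE]
      for (k in seq_len(nrow(mm))) {
        idx <- mm$frame[k]:min(n, mm$frame[k] +
                                 secToFrames(mm$duration[k], fr) - 1L)
        flow[idx] <- 0
      }
    }
    if (length(closedIdx) > 0) {
      src <- sched$start_frame[closedIdx[1]]:sched$end_frame[closedIdx[1]]
      replay <- flow[src]
      for (i in which(sched$condition == "open_loop")) {
        idx <- sched$start_frame[i]:sched$end_frame[i]
        flow[idx] <- rep_len(replay, length(idx))
      }
    }

    state <- as.numeric(v >= 0.25)
    smoothState <- expSmooth(state, config$pupilTau, fr)
    coupling <- config$pupilCoupling[cond]
    lum <- config$pupilLuminance[cond]
    pupil <- as.numeric(lum + coupling * smoothState +
                          rnorm(n, 0, config$pupilNoiseSd))
    face <- 0.6 * smoothState + rnorm(n, 0, 0.1)
    valid <- runif(n) >= config$blinkRate

    list(behavior = data.frame(velocity = v, flow = flow, pupil = pupil,
                               face = face, valid = valid, condition = cond,
                               stringsAsFactors = FALSE),
         bouts = bouts)
  })
}

#' Calcium impulse-response kernel
#'
#' Causal double-exponential kernel `exp(-t/decay) - exp(-t/rise)`,
#' normalized to unit sum so that a sustained unit drive produces a
#' steady-state response of 1. `decay = 0` yields a delta kernel.
#'
#' @param rise,decay time constants (s).
#' @param frameRate sampling rate (Hz).
#' @return numeric kernel vector.
#' @export
calciumKernel <- function(rise, decay, frameRate) {
  if (decay <= 0) return(1)
  tmax <- ceiling(6 * decay * frameRate)
  t <- (0:tmax) / frameRate
  k <- exp(-t / decay) - if (rise > 0) exp(-t / rise) else 0
  k / sum(k)
}

# Causal convolution keeping the input length.
causalConv <- function(x, k) {
  if (length(k) == 1L) return(x * k)
  as.numeric(stats::filter(x, k, method = "convolution", sides = 1)) ->
    out
  # stats::filter leaves leading NAs; fill by explicit partial sums
  nk <- length(k)
  for (i in seq_len(min(nk - 1L, length(x))))
    out[i] <- sum(k[seq_len(i)] * x[i:1])
  out
}

# Shift a trace right by `lag` frames, padding with its first value.
shiftTrace <- function(x, lag) {
  if (lag == 0L) return(x)
  n <- length(x)
  if (lag >= n) return(rep(x[1], n))
  if (lag > 0) c(rep(x[1], lag), x[seq_len(n - lag)])
  else c(x[(-lag + 1):n], rep(x[n], -lag))
}

allocateModels <- function(weights, nUnits) {
  w <- weights / sum(weights)
  counts <- floor(w * nUnits)
  rem <- nUnits - sum(counts)
  if (rem > 0) {
    extra <- order(w * nUnits - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(names(weights), counts)
}

#' Generate unit dF/F traces and the generator ground truth
#'
#' Builds, for each unit of the configured cohort, a noiseless drive
#' according to its coding model, convolves it with the calcium kernel, and
#' adds a per-site shared latent factor with locomotion-state dependent
#' loading plus private slow (AR(1)) and fast (white) noise.
#'
#' Coding models: `binary_state` units follow the threshold-binarized
#' velocity shifted by the state lag; `linear_velocity` units follow the
#' velocity itself (scaled so a typical bout peak gives drive ~ amplitude);
#' `visual` units respond to gratings with von-Mises orientation tuning,
#' multiplicative/additive locomotion gain, and (for layer-5-like units) a
#' latency shortened during locomotion; `mismatch` units respond to
#' visual-flow halts; `silent` units carry noise only.
#'
#' @param behavior result of [generateBehavior()].
#' @param schedule result of [generateSchedule()].
#' @param config a [synthConfig()].
#' @return list with `traces` (unit x frame dF/F matrix), `units`
#'   (data.frame of per-unit ground truth), `drive` (noiseless unit x frame
#'   drive matrix after kernel convolution), and `corrTargets` (data.frame
#'   of per-site, per-group pairwise-correlation targets by state).
#' @export
generateUnits <- function(behavior, schedule, config) {
  validateSynthConfig(config)
  fr <- config$frameRate
  v <- behavior$behavior$velocity
  n <- length(v)
  events <- schedule$events
  state <- as.numeric(v >= 0.25)
  lagFrames <- secToFrames(config$stateLag, fr)
  kern <- calciumKernel(config$kernelRise, config$kernelDecay, fr)
  vScale <- exp(config$peakVelocityMeanLog)
  nGroups <- length(config$sharedNoiseLoadingStationary)

  models <- allocateModels(config$codingModels, config$unitsPerSite)
  gratings <- if (!is.null(events) && nrow(events))
    events[events$event_type == "grating_onset", , drop = FALSE] else
    emptyEventTable()
  mismatches <- if (!is.null(events) && nrow(events))
    events[events$event_type == "mismatch", , drop = FALSE] else
    emptyEventTable()
  # locomotion state of each grating trial, by the analysis rule
  gratRun <- vapply(gratings$frame, function(f) {
    idx <- windowFrames(f, c(-0.5, 1), fr, n)
    length(idx) > 0 && all(v[idx] >= 0.25)
  }, logical(1))

  withSeed(subSeed(config$seed, "units"), {
    # arousal-like per-bout population gain, shared across units
    gainTrace <- rep(1, n)
    bouts <- behavior$bouts
    if (config$boutGainSd > 0 && nrow(bouts) > 0) {
      gB <- rlnorm(nrow(bouts), 0, config$boutGainSd)
      for (i in seq_len(nrow(bouts)))
        gainTrace[bouts$onset[i]:bouts$offset[i]] <- gB[i]
    }
    stateG <- state * gainTrace
    vG <- v * gainTrace
    nTotal <- config$nMice * config$sitesPerMouse * config$unitsPerSite
    traces <- matrix(0, nTotal, n)
    drive <- matrix(0, nTotal, n)
    units <- vector("list", nTotal)
    corrTargets <- NULL
    u <- 0L
    for (m in seq_len(config$nMice)) {
      for (s in seq_len(config$sitesPerMouse)) {
        siteId <- sprintf("m%02d_s%02d", m, s)
        zs <- replicate(nGroups, slowNoise(n, config$noiseAr),
                        simplify = FALSE)
        for (g in seq_len(nGroups)) {
          corrTargets <- rbind(corrTargets, data.frame(
            mouse = sprintf("m%02d", m), site = siteId, group = g,
            r_stationary = config$sharedNoiseLoadingStationary[g]^2,
            r_locomotion = config$sharedNoiseLoadingLocomotion[g]^2))
        }
        for (k in seq_len(config$unitsPerSite)) {
          u <- u + 1L
          model <- models[k]
          grp <- ((k - 1L) %% nGroups) + 1L
          amp <- config$amplitude *
            exp(rnorm(1, 0, config$amplitudeJitterSd))
          pref <- sample(c(0, 45, 90, 270, 180, 225, 270, 90), 1L)
          layer <- if (model %in% c("visual", "mismatch")) {
            if (runif(1) < config$layerL5Fraction) "L5" else "L23"
          } else "axon"
          dr <- numeric(n)
          if (model == "binary_state") {
            dr <- amp * causalConv(shiftTrace(stateG, lagFrames), kern)
          } else if (model == "linear_velocity") {
            dr <- amp * causalConv(shiftTrace(vG, lagFrames) / vScale, kern)
          } else if (model == "visual" && nrow(gratings) > 0) {
            box <- numeric(n)
            baseLat <- secToFrames(config$visualLatency, fr)
            for (ev in seq_len(nrow(gratings))) {
              run <- gratRun[ev]
              lat <- baseLat
              if (layer == "L5" && run)
                lat <- max(0L, baseLat - config$layer5Shortening)
              tune <- exp(config$tuningKappa *
                            (cos(2 * pi / 180 *
                                   (gratings$orientation[ev] - pref)) - 1))
              height <- amp * tune * (1 + config$responseGainMult * run) +
                config$responseGainAdd * run
              f0 <- gratings$frame[ev] + lat
              f1 <- min(n, gratings$frame[ev] +
                          secToFrames(gratings$duration[ev], fr) - 1L)
              if (f0 <= f1) box[f0:f1] <- box[f0:f1] + height
            }
            dr <- causalConv(box, kern)
          } else if (model == "mismatch" && nrow(mismatches) > 0) {
            box <- numeric(n)
            for (ev in seq_len(nrow(mismatches))) {
              f0 <- mismatches$frame[ev]
              f1 <- min(n, f0 + secToFrames(mismatches$duration[ev], fr) - 1L)
              box[f0:f1] <- box[f0:f1] + amp
            }
            dr <- causalConv(box, kern)
          }
          lam <- ifelse(state > 0,
                        config$sharedNoiseLoadingLocomotion[grp],
                        config$sharedNoiseLoadingStationary[grp])
          eps <- slowNoise(n, config$noiseAr)
          noise <- config$noiseSd * (lam * zs[[grp]] +
                                       sqrt(1 - lam^2) * eps)
          traces[u, ] <- dr + noise
          drive[u, ] <- dr
          units[[u]] <- data.frame(
            unit_id = sprintf("%s_u%03d", siteId, k),
            mouse = sprintf("m%02d", m), site = siteId,
            coding_model = model, amplitude = amp, pref_ori = pref,
            layer = layer, lag_s = config$stateLag, corr_group = grp,
            responsive = model %in% c("binary_state", "linear_velocity"),
            stringsAsFactors = FALSE)
        }
      }
    }
    units <- do.call(rbind, units)
    rownames(traces) <- units$unit_id
    rownames(drive) <- units$unit_id
    list(traces = traces, units = units, drive = drive,
         corrTargets = corrTargets)
  })
}

#' Synthesize raw fluorescence from dF/F traces
#'
#' Applies the forward model `F(t) = F0 * bleach(t) * (1 + dff(t)) + offset`
#' with a monotone non-increasing exponential bleach, so that the
#' percentile-filter drift correction of [computeDFF()] can be validated by
#' round trip.
#'
#' @param dffTraces unit x frame dF/F matrix.
#' @param config a [synthConfig()] (uses `bleachTau`, `F0`, `F0JitterSd`,
#'   `rawOffset`, `frameRate`, `seed`).
#' @return unit x frame raw-fluorescence matrix.
#' @export
generateRawFluorescence <- function(dffTraces, config) {
  validateSynthConfig(config)
  if (any(!is.finite(dffTraces))) stop("dff input must be finite")
  n <- ncol(dffTraces)
  t <- (seq_len(n) - 1) / config$frameRate
  bleach <- if (is.finite(config$bleachTau))
    exp(-t / config$bleachTau) else rep(1, n)
  withSeed(subSeed(config$seed, "raw"), {
    f0 <- config$F0 * exp(rnorm(nrow(dffTraces), 0, config$F0JitterSd))
    out <- sweep(1 + dffTraces, 1, f0, `*`)
    out <- sweep(out, 2, bleach, `*`) + config$rawOffset
    rownames(out) <- rownames(dffTraces)
    out
  })
}

#' Simulate a complete synthetic session
#'
#' Orchestrates [generateSchedule()], [generateBehavior()],
#' [generateUnits()] and optionally [generateRawFluorescence()], and
#' assembles a [CalciumSession-class] whose metadata carries the full
#' generator ground truth (unit table, bout table, correlation targets,
#' noiseless drive).
#'
#' @param config a [synthConfig()].
#' @param makeRaw also synthesize the `"raw"` assay.
#' @return a `CalciumSession`.
#' @export
simulateSession <- function(config = synthConfig(), makeRaw = FALSE) {
  sch <- generateSchedule(config)
  beh <- generateBehavior(config, sch)
  un <- generateUnits(beh, sch, config)
  gt <- list(units = un$units, bouts = beh$bouts,
             corr_targets = un$corrTargets, drive = un$drive,
             config = config)
  sess <- CalciumSession(un$traces, kind = "dff",
                         frameRate = config$frameRate,
                         behavior = beh$behavior, unitData = un$units,
                         schedule = sch$schedule, events = sch$events,
                         groundTruth = gt)
  if (makeRaw) {
    raw <- generateRawFluorescence(un$traces, config)
    SummarizedExperiment::assay(sess, "raw", withDimnames = FALSE) <- raw
  }
  sess
}
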