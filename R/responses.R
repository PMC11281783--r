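# Event-triggered quantification: average responses, responsiveness,
# latencies, velocity tuning, binarization comparison, bout and tuning
# analyses.

#' Event-triggered snippet matrices and response scalars
#'
#' Extracts, for every unit and event, the dF/F snippet in a half-open
#' window around the event, and computes per-event baseline-window and
#' response-window means, the baseline-subtracted mean trace, and the
#' per-unit response scalar (mean over events of response-window mean minus
#' baseline mean). Events whose window leaves the recording are dropped.
#'
#' @param traces unit x frame dF/F matrix, or a [CalciumSession-class].
#' @param eventFrames integer event frames (1-based).
#' @param frameRate sampling rate (Hz); taken from the session if given.
#' @param window snippet window in seconds, half-open `[w1, w2)`.
#' @param baseline baseline window in seconds (default -1 to -0.5 s; use
#'   -0.5 to 0 s for mismatch so the locomotion-related response is part of
#'   the baseline).
#' @param response response window in seconds (default +0.5 to +1.5 s).
#' @param unitData optional per-unit annotation (mouse/site/unit_id).
#' @return an [ETAResult-class].
#' @export
eventTriggeredMatrix <- function(traces, eventFrames, frameRate = NULL,
                                 window = c(-2, 3),
                                 baseline = c(-1, -0.5),
                                 response = c(0.5, 1.5),
                                 unitData = NULL) {
  if (is(traces, "CalciumSession")) {
    if (is.null(unitData)) unitData <- SummarizedExperiment::rowData(traces)
    frameRate <- frameRate(traces)
    traces <- dff(traces)
  }
  if (is.null(frameRate)) stop("frameRate is required with matrix input")
  traces <- as.matrix(traces)
  n <- ncol(traces)
  offs <- windowOffsets(window, frameRate)
  keep <- eventFrames[eventFrames + offs[1] >= 1L &
                        eventFrames + offs[length(offs)] <= n]
  if (length(keep) == 0L)
    stop("no event with a fully in-bounds analysis window")
  nU <- nrow(traces); nE <- length(keep); nT <- length(offs)
  snip <- array(NA_real_, c(nU, nE, nT),
                dimnames = list(rownames(traces), NULL, NULL))
  for (e in seq_len(nE))
    snip[, e, ] <- traces[, keep[e] + offs, drop = FALSE]
  tAxis <- offs / frameRate
  inBase <- tAxis >= baseline[1] & tAxis < baseline[2]
  inResp <- tAxis >= response[1] & tAxis < response[2]
  baseM <- apply(snip[, , inBase, drop = FALSE], c(1, 2), mean)
  respM <- apply(snip[, , inResp, drop = FALSE], c(1, 2), mean)
  meanTr <- apply(snip, c(1, 3), mean)
  meanTr <- meanTr - rowMeans(meanTr[, inBase, drop = FALSE])
  if (is.null(unitData))
    unitData <- S4Vectors::DataFrame(unit_id = rownames(traces) %||%
                                       as.character(seq_len(nU)))
  new("ETAResult", snippets = snip, time = tAxis, window = window,
      baselineWindow = baseline, responseWindow = response,
      meanTrace = meanTr, baselineMeans = baseM, responseMeans = respM,
      response = rowMeans(respM - baseM),
      nOnsets = rep(as.integer(nE), nU),
      unitData = S4Vectors::DataFrame(unitData), frameRate = frameRate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify units as responsive to an event
#'
#' A unit is responsive if its per-event response-window means differ from
#' its per-event baseline means by a paired two-sample t-test at
#' `p < alpha`. Units with fewer than `minOnsets` events are excluded
#' (flag `NA`, not `FALSE`). Degenerate zero-variance differences are
#' decided by a tie rule: identical non-zero differences count as
#' responsive, identical zero differences as not responsive.
#'
#' @param eta an [ETAResult-class].
#' @param alpha significance level.
#' @param minOnsets minimum number of events per unit.
#' @return logical per-unit vector (NA = excluded).
#' @export
classifyResponsive <- function(eta, alpha = 0.05, minOnsets = 5L) {
  nU <- nrow(eta@meanTrace)
  out <- rep(NA, nU)
  for (i in seq_len(nU)) {
    if (eta@nOnsets[i] < minOnsets) next
    d <- eta@responseMeans[i, ] - eta@baselineMeans[i, ]
    if (sd(d) == 0) {
      out[i] <- d[1] != 0
    } else {
      out[i] <- t.test(eta@responseMeans[i, ], eta@baselineMeans[i, ],
                       paired = TRUE)$p.value < alpha
    }
  }
  out
}

#' Per-site fraction of responsive units
#'
#' @param flags logical responsiveness flags (NA = excluded unit).
#' @param sites site label per unit.
#' @param alpha the test level, reported as the chance fraction.
#' @return list with `fractions` (named per-site fraction among eligible
#'   units), `chance` (= alpha), `nEligible` per site.
#' @export
responsiveFractionBySite <- function(flags, sites, alpha = 0.05) {
  ok <- !is.na(flags)
  fr <- c(tapply(flags[ok], sites[ok], mean))
  nE <- c(tapply(flags[ok], sites[ok], length))
  list(fractions = fr, chance = alpha,
       nEligible = nE, mean = mean(fr), sem = sd(fr) / sqrt(length(fr)))
}

#' Null band of the population response from random locomotion triggers
#'
#' Draws `nDraws` random triggers during locomotion, extracts the
#' baseline-subtracted population-mean snippet at each, and returns the
#' per-timepoint 95 percent percentile confidence band of the mean trace
#' (percentile bootstrap over the drawn triggers), against which real
#' event-triggered responses can be compared.
#'
#' @param traces unit x frame dF/F matrix.
#' @param velocityTrace velocity (cm/s).
#' @param frameRate sampling rate (Hz).
#' @param nDraws number of random triggers.
#' @param window,baseline snippet and baseline windows (s).
#' @param nBoot bootstrap replicates for the band.
#' @param seed optional RNG seed.
#' @return list with `time`, `lower`, `upper`, `mean`.
#' @export
randomTriggerNullBand <- function(traces, velocityTrace, frameRate,
                                  nDraws = 100L, window = c(-2, 3),
                                  baseline = c(-1, -0.5), nBoot = 1000L,
                                  seed = NULL) {
  withSeed(seed, {
    trig <- drawRandomTriggers(velocityTrace, nDraws, frameRate,
                               edgeWindow = window)
    pop <- colMeans(as.matrix(traces))
    offs <- windowOffsets(window, frameRate)
    tAxis <- offs / frameRate
    inBase <- tAxis >= baseline[1] & tAxis < baseline[2]
    snips <- t(vapply(trig$frame, function(f) {
      s <- pop[f + offs]
      s - mean(s[inBase])
    }, numeric(length(offs))))
    bootIdx <- matrix(sample.int(nDraws, nBoot * nDraws, replace = TRUE),
                      nBoot)
    bm <- t(apply(bootIdx, 1, function(ix) colMeans(snips[ix, , drop = FALSE])))
    list(time = tAxis,
         lower = apply(bm, 2, quantile, 0.025),
         upper = apply(bm, 2, quantile, 0.975),
         mean = colMeans(snips))
  })
}

# Shared latency rule: first time in `search` where the unit's mean trace
# is >= baselineMean + kSd * baselineSD on every frame of [t, t + hold).
latencyFromMeanTrace <- function(eta, kSd, hold, search) {
  fr <- eta@frameRate
  holdF <- secToFrames(hold, fr)
  tAxis <- eta@time
  inBase <- tAxis >= eta@baselineWindow[1] & tAxis < eta@baselineWindow[2]
  nU <- nrow(eta@meanTrace)
  lat <- rep(NA_real_, nU)
  for (i in seq_len(nU)) {
    tr <- eta@meanTrace[i, ]
    bm <- mean(tr[inBase])
    bs <- sd(tr[inBase])
    if (is.na(bs) || bs == 0) {
      warning("zero baseline SD; latency undefined for unit ", i)
      next
    }
    thr <- bm + kSd * bs
    cand <- which(tAxis >= search[1] & tAxis <= search[2])
    # the hold must fit inside both the search window and the snippet
    cand <- cand[cand + holdF - 1L <= length(tr) &
                   tAxis[pmin(cand + holdF - 1L, length(tr))] <= search[2]]
    for (j in cand) {
      if (all(tr[j:(j + holdF - 1L)] >= thr)) { lat[i] <- tAxis[j]; break }
    }
  }
  lat
}

#' Latency of the locomotion-onset response
#'
#' The time after onset at which the across-onset mean trace first reaches
#' 2 baseline SDs above the baseline mean and stays there for at least 1 s.
#' Units that never cross within the search window, or that are not
#' responsive (when `responsive` is supplied), are excluded (NA).
#'
#' @param eta an [ETAResult-class] for locomotion onsets.
#' @param kSd threshold in baseline SDs.
#' @param hold minimum supra-threshold duration (s).
#' @param search search window (s) relative to onset.
#' @param responsive optional logical flags from [classifyResponsive()];
#'   non-responsive units get NA.
#' @return numeric per-unit latency (s), NA where undefined.
#' @export
onsetLatency <- function(eta, kSd = 2, hold = 1, search = c(-2, 3),
                         responsive = NULL) {
  lat <- latencyFromMeanTrace(eta, kSd, hold, search)
  if (!is.null(responsive)) lat[!responsive %in% TRUE] <- NA_real_
  lat
}

#' Latency of the grating response
#'
#' As [onsetLatency()] but with the grating criteria: threshold hold of
#' 1/3 s and a search window of 0 to +2 s (the grating duration); units
#' that never cross are excluded.
#'
#' @inheritParams onsetLatency
#' @return numeric per-unit latency (s), NA where undefined.
#' @export
gratingLatency <- function(eta, kSd = 2, hold = 1 / 3, search = c(0, 2)) {
  latencyFromMeanTrace(eta, kSd, hold, search)
}

#' Velocity tuning curve with hierarchical-bootstrap confidence bands
#'
#' Bins locomotion velocity into `nBins` evenly spaced bins over
#' `range` (100 bins over 0 to 6.25 cm/s), averages each unit's activity
#' within each bin, and summarizes each bin across the population with the
#' nested hierarchical bootstrap (sites -> units): the bootstrap median of
#' the mean and its 95 percent CI. Bins without frames are NA, not zero.
#'
#' @param traces unit x frame dF/F matrix.
#' @param velocityTrace velocity (cm/s).
#' @param sites site label per unit.
#' @param frameRate sampling rate (Hz) (unused in binning; kept for
#'   interface symmetry).
#' @param nBins number of bins.
#' @param range velocity range covered by the bins (cm/s).
#' @param nBoot bootstrap replicates per bin.
#' @param seed optional RNG seed.
#' @return data.frame: `bin_lo`, `bin_hi`, `bin_mid`, `n_frames`,
#'   `median`, `ci_lo`, `ci_hi`.
#' @export
velocityTuningCurve <- function(traces, velocityTrace, sites,
                                frameRate = 15, nBins = 100L,
                                range = c(0, 6.25), nBoot = 1000L,
                                seed = NULL) {
  traces <- as.matrix(traces)
  edges <- seq(range[1], range[2], length.out = nBins + 1L)
  binIdx <- findInterval(velocityTrace, edges, rightmost.closed = TRUE)
  inRange <- binIdx >= 1L & binIdx <= nBins
  counts <- tabulate(binIdx[inRange], nBins)
  # per-unit per-bin mean: sum per bin / count
  sums <- matrix(0, nrow(traces), nBins)
  sel <- which(inRange)
  agg <- rowsum(t(traces[, sel, drop = FALSE]), group = binIdx[sel])
  sums[, as.integer(rownames(agg))] <- t(agg)
  unitMeans <- sweep(sums, 2, pmax(counts, 1L), `/`)
  unitMeans[, counts == 0L] <- NA_real_
  out <- data.frame(bin_lo = edges[-(nBins + 1L)], bin_hi = edges[-1],
                    bin_mid = (edges[-1] + edges[-(nBins + 1L)]) / 2,
                    n_frames = counts, median = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_)
  withSeed(seed, {
    for (b in which(counts > 0L)) {
      res <- hierarchicalBootstrapMean(split(unitMeans[, b], sites),
                                       nResamples = nBoot)
      out$median[b] <- median(bootMeans(res))
      out$ci_lo[b] <- bootCI(res)[1]
      out$ci_hi[b] <- bootCI(res)[2]
    }
  })
  out
}

#' Binary-state versus linear-velocity model comparison
#'
#' For every unit, the Pearson correlation of its activity with locomotion
#' velocity and with the threshold-binarized velocity, over the same valid
#' frames. Units of a binary state coder correlate better with the
#' binarized regressor; linear velocity coders the reverse.
#'
#' @param traces unit x frame dF/F matrix.
#' @param velocityTrace velocity (cm/s).
#' @param threshold binarization threshold (cm/s).
#' @param valid optional logical frame mask.
#' @return data.frame: `unit_id`, `r_velocity`, `r_binary` (NA when a
#'   regressor has zero variance).
#' @export
binarizationComparison <- function(traces, velocityTrace, threshold = 0.25,
                                   valid = NULL) {
  traces <- as.matrix(traces)
  if (is.null(valid)) valid <- rep(TRUE, length(velocityTrace))
  v <- velocityTrace[valid]
  b <- binarizeVelocity(v, threshold)
  rv <- if (sd(v) == 0) rep(NA_real_, nrow(traces)) else
    as.numeric(cor(t(traces[, valid, drop = FALSE]), v))
  rb <- if (sd(b) == 0) rep(NA_real_, nrow(traces)) else
    as.numeric(cor(t(traces[, valid, drop = FALSE]), b))
  data.frame(unit_id = rownames(traces) %||%
               as.character(seq_len(nrow(traces))),
             r_velocity = rv, r_binary = rb)
}

#' Bout-by-bout correlation of onset and offset responses
#'
#' For each bout: the onset response is the mean population activity (or
#' velocity) +0.5 to +1.5 s after locomotion onset, the offset response the
#' mean over -1.5 to -0.5 s before locomotion offset, both relative to the
#' same pre-onset baseline (-1 to -0.5 s). Returns the Pearson correlation
#' across bouts, computed separately for population activity and for
#' velocity. A state coder holds its activity across the bout (high r)
#' while velocity declines within bouts (lower r).
#'
#' @param traces unit x frame dF/F matrix (population of one site).
#' @param velocityTrace velocity (cm/s).
#' @param bouts bout table from [segmentBouts()].
#' @param frameRate sampling rate (Hz).
#' @param onsetWindow,offsetWindow,baseline windows (s).
#' @param minBouts minimum number of usable bouts.
#' @return list with `r_activity`, `r_velocity`, `n_bouts`, and the
#'   per-bout response table.
#' @export
boutResponseCorrelation <- function(traces, velocityTrace, bouts, frameRate,
                                    onsetWindow = c(0.5, 1.5),
                                    offsetWindow = c(-1.5, -0.5),
                                    baseline = c(-1, -0.5),
                                    minBouts = 3L) {
  pop <- colMeans(as.matrix(traces))
  n <- length(pop)
  rows <- lapply(seq_len(nrow(bouts)), function(i) {
    onF <- bouts$onset[i]; offF <- bouts$offset[i]
    iBase <- windowFrames(onF, baseline, frameRate, n)
    iOn <- windowFrames(onF, onsetWindow, frameRate, n)
    iOff <- windowFrames(offF, offsetWindow, frameRate, n)
    if (!length(iBase) || !length(iOn) || !length(iOff)) return(NULL)
    data.frame(act_on = mean(pop[iOn]) - mean(pop[iBase]),
               act_off = mean(pop[iOff]) - mean(pop[iBase]),
               vel_on = mean(velocityTrace[iOn]) - mean(velocityTrace[iBase]),
               vel_off = mean(velocityTrace[iOff]) - mean(velocityTrace[iBase]))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < minBouts)
    stop(sprintf("need at least %d usable bouts, got %d", minBouts,
                 if (is.null(tab)) 0L else nrow(tab)))
  list(r_activity = cor(tab$act_on, tab$act_off),
       r_velocity = cor(tab$vel_on, tab$vel_off),
       n_bouts = nrow(tab), responses = tab)
}

#' Split-half selection of the most responsive units
#'
#' Selects the top `fraction` of units by their mean response over a random
#' half of the trials (selection half); reported held-out responses use
#' only the remaining trials, so selection and reporting never share
#' trials.
#'
#' @param eta an [ETAResult-class] (typically built with response window
#'   +0.5 to +2.0 s and baseline -0.5 to 0 s).
#' @param fraction fraction of units to select.
#' @param seed optional RNG seed for the trial split.
#' @return list with `selected` (unit indices), `selectionTrials`,
#'   `heldOutTrials`, `heldOutResponse` (per selected unit), and
#'   `selectionResponse`.
#' @export
splitHalfTopResponders <- function(eta, fraction = 0.10, seed = NULL) {
  nE <- dim(eta@snippets)[2]
  nU <- dim(eta@snippets)[1]
  withSeed(seed, {
    sel <- sort(sample.int(nE, floor(nE / 2)))
    held <- setdiff(seq_len(nE), sel)
    d <- eta@responseMeans - eta@baselineMeans
    selResp <- rowMeans(d[, sel, drop = FALSE])
    k <- max(1L, round(fraction * nU))
    top <- order(selResp, decreasing = TRUE)[seq_len(k)]
    list(selected = sort(top), selectionTrials = sel, heldOutTrials = held,
         heldOutResponse = rowMeans(d[sort(top), held, drop = FALSE]),
         selectionResponse = selResp)
  })
}

#' Additive/multiplicative gain decomposition of orientation tuning
#'
#' Determines each unit's preferred orientation from a random half of the
#' stationary trials, builds population tuning curves versus orientation
#' relative to preferred (held-out stationary trials and each comparison
#' condition), and regresses the condition tuning curve on the stationary
#' one across orientation bins: the slope is the multiplicative gain, the
#' intercept the additive offset.
#'
#' @param responses unit x trial matrix of baseline-subtracted responses.
#' @param orientation trial orientation labels (degrees).
#' @param condition trial condition labels; `"stationary"` is the
#'   reference.
#' @param seed optional RNG seed for the stationary-trial split.
#' @return list with `gains` (data.frame: condition, slope, intercept),
#'   `tuning` (orientation-relative population curves), `preferred`
#'   (per-unit preferred orientation).
#' @export
orientationGainDecomposition <- function(responses, orientation, condition,
                                         seed = NULL) {
  responses <- as.matrix(responses)
  oris <- sort(unique(orientation))
  if (length(oris) < 2L)
    stop("gain decomposition needs at least 2 distinct orientations")
  statTrials <- which(condition == "stationary")
  if (length(statTrials) < 2L) stop("need stationary trials for reference")
  withSeed(seed, {
    selHalf <- sort(sample(statTrials, floor(length(statTrials) / 2)))
    heldStat <- setdiff(statTrials, selHalf)
    # preferred orientation: max mean response in the selection half;
    # ties broken toward the lower orientation value
    pref <- apply(responses[, selHalf, drop = FALSE], 1, function(r) {
      m <- tapply(r, orientation[selHalf], mean)
      oo <- as.numeric(names(m))
      oo[which.max(m)]
    })
    relOri <- function(o, p) {
      d <- (o - p) %% 360
      ifelse(d > 180, d - 360, d)
    }
    curveFor <- function(trials) {
      # population curve: mean over units of per-unit relative-orientation
      # bin means
      bins <- sort(unique(unlist(lapply(seq_len(nrow(responses)), function(i)
        relOri(orientation[trials], pref[i])))))
      curves <- t(vapply(seq_len(nrow(responses)), function(i) {
        ro <- relOri(orientation[trials], pref[i])
        m <- tapply(responses[i, trials], factor(ro, levels = bins), mean)
        as.numeric(m)
      }, numeric(length(bins))))
      list(bins = bins, curve = colMeans(curves, na.rm = TRUE))
    }
    ref <- curveFor(heldStat)
    conds <- setdiff(unique(condition), "stationary")
    gains <- do.call(rbind, lapply(conds, function(cc) {
      cv <- curveFor(which(condition == cc))
      shared <- intersect(ref$bins, cv$bins)
      x <- ref$curve[match(shared, ref$bins)]
      y <- cv$curve[match(shared, cv$bins)]
      ok <- is.finite(x) & is.finite(y)
      fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
      data.frame(condition = cc, intercept = fit$coefficients[1],
                 slope = fit$coefficients[2])
    }))
    rownames(gains) <- NULL
    list(gains = gains,
         tuning = list(stationary = ref),
         preferred = pref)
  })
}

#' Condition-wise correlation of population activity with behavior
#'
#' Pearson correlation between the mean population activity (or any trace)
#' and a behavior channel, restricted to the frames of each condition and
#' to valid frames (blink-free for pupil). For pupil analyses, conditions
#' with less than `minPupilSeconds` of valid data are excluded (NA).
#'
#' @param activity numeric trace (e.g. `colMeans(dff(session))`).
#' @param channel behavior trace of equal length.
#' @param conditionLabels per-frame condition labels.
#' @param valid logical frame mask.
#' @param frameRate sampling rate (Hz).
#' @param isPupil apply the 30-s minimum-data rule.
#' @param minPupilSeconds minimum valid data per condition for pupil.
#' @return named numeric vector of per-condition correlations.
#' @export
conditionBehaviorCorrelation <- function(activity, channel, conditionLabels,
                                         valid = NULL, frameRate = 15,
                                         isPupil = FALSE,
                                         minPupilSeconds = 30) {
  if (is.null(valid)) valid <- rep(TRUE, length(activity))
  conds <- unique(conditionLabels[!is.na(conditionLabels)])
  out <- stats::setNames(rep(NA_real_, length(conds)), conds)
  for (cc in conds) {
    idx <- which(conditionLabels == cc & valid)
    if (isPupil && length(idx) < minPupilSeconds * frameRate) next
    if (length(idx) < 3L) next
    if (sd(activity[idx]) == 0 || sd(channel[idx]) == 0) next
    out[cc] <- cor(activity[idx], channel[idx])
  }
  out
}
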