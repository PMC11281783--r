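#' Binarize a velocity trace into a locomotion-state trace
#'
#' @param velocity numeric velocity trace (cm/s).
#' @param threshold state threshold in cm/s; "above" means `v >= threshold`.
#' @return numeric 0/1 trace.
#' @export
binarizeVelocity <- function(velocity, threshold = 0.25) {
  as.numeric(velocity >= threshold)
}

# Run-length representation of the above-threshold indicator.
thresholdRuns <- function(velocity, threshold) {
  r <- rle(velocity >= threshold)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = c(1L, head(ends, -1) + 1L),
             end = as.integer(ends), len = r$lengths)
}

# Shared onset/offset detector. An "onset" (directed crossing into `into`)
# at frame f requires the indicator to equal `into` on every frame of
# [f, f + hold) and to equal !into on every frame of [f - prior, f).
# Crossings whose hold/prior or whose downstream analysis window
# (edgeWindow, in seconds around the event) leave the recording are
# excluded.
detectCrossings <- function(velocity, threshold, hold, prior, frameRate,
                            into, edgeWindow) {
  if (hold <= 0 || prior <= 0) stop("hold and prior durations must be > 0")
  n <- length(velocity)
  holdF <- secToFrames(hold, frameRate)
  priorF <- secToFrames(prior, frameRate)
  runs <- thresholdRuns(velocity, threshold)
  cand <- integer(0)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] != into || runs$len[i] < holdF) next
    if (i == 1L) next                       # no prior run inside recording
    if (runs$len[i - 1L] < priorF) next
    cand <- c(cand, runs$start[i])
  }
  if (length(cand) && !is.null(edgeWindow)) {
    lo <- secToFrames(edgeWindow[1], frameRate)
    hi <- secToFrames(edgeWindow[2], frameRate)
    cand <- cand[cand + lo >= 1L & cand + hi - 1L <= n]
  }
  cand
}

#' Detect locomotion onsets
#'
#' A locomotion onset is the first frame of a run with velocity at or above
#' `threshold` lasting at least `hold` seconds, preceded by at least
#' `quiet` seconds below threshold. Events whose downstream analysis window
#' (`edgeWindow`, default -2 s to +3 s) leaves the recording are excluded.
#'
#' @param velocity velocity trace (cm/s).
#' @param frameRate sampling rate (Hz).
#' @param threshold state threshold (cm/s).
#' @param hold minimum above-threshold duration (s).
#' @param quiet minimum preceding below-threshold duration (s).
#' @param edgeWindow analysis window (s, relative to event) that must lie
#'   inside the recording; NULL disables the exclusion.
#' @param condition optional per-frame condition labels to annotate events.
#' @return an event table (see [emptyEventTable()] for columns).
#' @export
detectLocomotionOnsets <- function(velocity, frameRate, threshold = 0.25,
                                   hold = 1, quiet = 1,
                                   edgeWindow = c(-2, 3),
                                   condition = NULL) {
  f <- detectCrossings(velocity, threshold, hold, quiet, frameRate,
                       into = TRUE, edgeWindow = edgeWindow)
  makeEventTable("locomotion_onset", f, frameRate,
                 condition = if (is.null(condition)) NA_character_
                             else condition[f])
}

#' Detect locomotion offsets
#'
#' Mirror image of [detectLocomotionOnsets()]: the first frame of a run
#' below `threshold` lasting at least `hold` seconds, preceded by at least
#' `prior` seconds at or above threshold.
#'
#' @inheritParams detectLocomotionOnsets
#' @param prior minimum preceding above-threshold duration (s).
#' @return an event table.
#' @export
detectLocomotionOffsets <- function(velocity, frameRate, threshold = 0.25,
                                    hold = 1, prior = 1,
                                    edgeWindow = c(-2, 3),
                                    condition = NULL) {
  f <- detectCrossings(velocity, threshold, hold, prior, frameRate,
                       into = FALSE, edgeWindow = edgeWindow)
  makeEventTable("locomotion_offset", f, frameRate,
                 condition = if (is.null(condition)) NA_character_
                             else condition[f])
}

#' Detect visual-flow onsets in the open-loop condition
#'
#' Applies the locomotion-onset criteria to the visual flow speed,
#' restricted to frames labeled `open_loop`.
#'
#' @param flowSpeed visual flow speed trace.
#' @param condition per-frame condition labels.
#' @inheritParams detectLocomotionOnsets
#' @return an event table with `event_type = "visual_flow_onset"`.
#' @export
detectVisualFlowOnsets <- function(flowSpeed, frameRate, condition,
                                   threshold = 0.25, hold = 1, quiet = 1,
                                   edgeWindow = c(-2, 3)) {
  f <- detectCrossings(flowSpeed, threshold, hold, quiet, frameRate,
                       into = TRUE, edgeWindow = edgeWindow)
  f <- f[condition[f] == "open_loop"]
  makeEventTable("visual_flow_onset", f, frameRate, condition = "open_loop")
}

#' Segment locomotion bouts from onset and offset events
#'
#' Pairs each locomotion onset with the next offset; onset/offset pairs
#' separated by less than `minSeparation` seconds are discarded. Offsets
#' preceding the first onset are skipped (with a message).
#'
#' @param onsets,offsets event tables from [detectLocomotionOnsets()] /
#'   [detectLocomotionOffsets()] computed on the same velocity trace.
#' @param frameRate sampling rate (Hz).
#' @param minSeparation minimum onset-to-offset separation (s).
#' @return data.frame of bouts: `onset`, `offset` (frames), `duration_s`.
#' @export
segmentBouts <- function(onsets, offsets, frameRate, minSeparation = 4) {
  on <- onsets$frame
  off <- offsets$frame
  skipped <- sum(off < if (length(on)) on[1] else Inf)
  if (skipped > 0)
    message(sprintf("segmentBouts: skipping %d offset(s) before first onset",
                    skipped))
  bOn <- integer(0); bOff <- integer(0)
  i <- 1L
  for (f in on) {
    nxt <- off[off > f]
    if (length(nxt) == 0L) next
    o <- nxt[1]
    if (length(bOff) && f <= tail(bOff, 1)) next   # onset inside prior bout
    if ((o - f) / frameRate < minSeparation) next
    bOn <- c(bOn, f); bOff <- c(bOff, o)
  }
  data.frame(onset = bOn, offset = bOff,
             duration_s = (bOff - bOn) / frameRate)
}

#' Filter visuomotor-mismatch events by uninterrupted locomotion
#'
#' Keeps a mismatch event only if velocity is at or above `threshold` on
#' every frame from 0.5 s before to 1 s after the event onset; events whose
#' window leaves the recording are dropped.
#'
#' @param mismatchEvents event table of mismatch onsets.
#' @param velocity velocity trace (cm/s).
#' @param frameRate sampling rate (Hz).
#' @param threshold locomotion threshold (cm/s).
#' @param window gating window in seconds relative to onset.
#' @return the filtered event table, with `state = "locomotion"`.
#' @export
filterMismatchEvents <- function(mismatchEvents, velocity, frameRate,
                                 threshold = 0.25, window = c(-0.5, 1)) {
  if (nrow(mismatchEvents) == 0L) return(mismatchEvents)
  n <- length(velocity)
  keep <- vapply(mismatchEvents$frame, function(f) {
    idx <- windowFrames(f, window, frameRate, n)
    length(idx) > 0 && all(velocity[idx] >= threshold)
  }, logical(1))
  out <- mismatchEvents[keep, , drop = FALSE]
  out$state <- rep_len("locomotion", nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify the locomotion state of a trial
#'
#' A stimulus instance occurs during "locomotion" if velocity is at or
#' above `threshold` on every frame of the window (-0.5 s to +1 s from
#' stimulus onset); otherwise it is "stationary".
#'
#' @param eventFrames integer event frames.
#' @param velocity velocity trace (cm/s).
#' @param frameRate sampling rate (Hz).
#' @param threshold locomotion threshold (cm/s).
#' @param window classification window (s).
#' @return character vector, `"locomotion"` or `"stationary"` per event
#'   (`"stationary"` also when the window leaves the recording).
#' @export
classifyTrialState <- function(eventFrames, velocity, frameRate,
                               threshold = 0.25, window = c(-0.5, 1)) {
  n <- length(velocity)
  vapply(eventFrames, function(f) {
    idx <- windowFrames(f, window, frameRate, n)
    if (length(idx) > 0 && all(velocity[idx] >= threshold))
      "locomotion" else "stationary"
  }, character(1))
}

#' Draw random triggers during locomotion
#'
#' Samples `n` frames uniformly without replacement from frames classified
#' as locomotion (binarized velocity = 1) whose analysis window lies fully
#' inside the recording. Used to build the random-trigger null band.
#'
#' @param velocity velocity trace (cm/s).
#' @param n number of triggers.
#' @param frameRate sampling rate (Hz).
#' @param threshold locomotion threshold (cm/s).
#' @param edgeWindow analysis window (s) that must fit inside the
#'   recording.
#' @param seed optional RNG seed for a reproducible draw.
#' @return an event table with `event_type = "random_trigger"`.
#' @export
drawRandomTriggers <- function(velocity, n, frameRate, threshold = 0.25,
                               edgeWindow = c(-2, 3), seed = NULL) {
  if (n < 1L) stop("n must be at least 1")
  nf <- length(velocity)
  lo <- secToFrames(edgeWindow[1], frameRate)
  hi <- secToFrames(edgeWindow[2], frameRate)
  pool <- which(velocity >= threshold)
  pool <- pool[pool + lo >= 1L & pool + hi - 1L <= nf]
  if (length(pool) == 0L) stop("no locomotion frames available for triggers")
  if (n > length(pool))
    stop(sprintf("requested %d triggers but only %d frames available",
                 n, length(pool)))
  f <- withSeed(seed, sort(sample(pool, n)))
  makeEventTable("random_trigger", f, frameRate, state = "locomotion")
}

#' Detect all standard events of a session
#'
#' Convenience wrapper running locomotion onset/offset detection, bout
#' segmentation, visual-flow onset detection, mismatch filtering and
#' grating trial-state classification on a [CalciumSession-class], merging
#' the results with the session's stimulus events.
#'
#' @param session a `CalciumSession`.
#' @param threshold locomotion threshold (cm/s).
#' @return the session with its event table replaced and a `bouts` entry
#'   added to `metadata()`.
#' @export
detectSessionEvents <- function(session, threshold = 0.25) {
  fr <- frameRate(session)
  v <- velocity(session)
  cond <- behaviorChannel(session, "condition")
  ons <- detectLocomotionOnsets(v, fr, threshold, condition = cond)
  offs <- detectLocomotionOffsets(v, fr, threshold, condition = cond)
  bouts <- segmentBouts(ons, offs, fr)
  stim <- sessionEvents(session)
  flowOns <- if ("flow" %in% colnames(SummarizedExperiment::colData(session)))
    detectVisualFlowOnsets(behaviorChannel(session, "flow"), fr, cond,
                           threshold) else NULL
  mm <- stim[stim$event_type == "mismatch", , drop = FALSE]
  mmKept <- filterMismatchEvents(mm, v, fr, threshold)
  other <- stim[stim$event_type != "mismatch", , drop = FALSE]
  if (nrow(other) > 0)
    other$state <- classifyTrialState(other$frame, v, fr, threshold)
  ev <- bindEventTables(other, mmKept, ons, offs, flowOns)
  S4Vectors::metadata(session)$events <- ev
  S4Vectors::metadata(session)$bouts <- bouts
  session
}
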