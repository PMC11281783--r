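# Orchestration, configuration and session I/O.

#' Analysis configuration with the study's standard parameters
#'
#' Collects every threshold and window used across the pipeline, at the
#' standard defaults: locomotion threshold 0.25 cm/s with 1 s hold/quiet,
#' 4 s bout separation, event window -2 to +3 s with baseline -1 to -0.5 s
#' (mismatch baseline -0.5 to 0 s) and response +0.5 to +1.5 s, split-half
#' selection windows +0.5 to +2 s / -0.5 to 0 s, 100 velocity bins over
#' 0 to 6.25 cm/s, 15 s minimum per state for correlation analyses, 30 s
#' minimum pupil data per condition, 10000 bootstrap resamples (1000 for
#' trace bins), test level 0.05.
#'
#' @param ... overrides for any default field.
#' @return list of class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    threshold = 0.25, hold = 1, quiet = 1, boutSeparation = 4,
    window = c(-2, 3), baseline = c(-1, -0.5),
    mismatchBaseline = c(-0.5, 0), response = c(0.5, 1.5),
    selectionResponse = c(0.5, 2), selectionBaseline = c(-0.5, 0),
    latencyKSd = 2, latencyHold = 1, latencySearch = c(-2, 3),
    gratingLatencyHold = 1 / 3, gratingLatencySearch = c(0, 2),
    nVelocityBins = 100L, velocityRange = c(0, 6.25),
    minOnsets = 5L, minStateSeconds = 15, minPupilSeconds = 30,
    alpha = 0.05, nResamples = 10000L, nTraceResamples = 1000L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown analysis parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Run the full session analysis
#'
#' Executes the pipeline stages in order (event detection, event-triggered
#' responses and responsiveness, latency, bout analysis, velocity tuning,
#' binarization comparison, condition-wise behavior correlations,
#' state-resolved pairwise correlations, hierarchical-bootstrap tests) and
#' returns all result tables with provenance.
#'
#' @param session a [CalciumSession-class] with a `"dff"` assay.
#' @param config an [analysisConfig()].
#' @return list of class `"RunReport"`: result tables, a statistics log,
#'   the config, and a provenance block (config/seed/content hash).
#' @export
runFullAnalysis <- function(session, config = analysisConfig()) {
  fr <- frameRate(session)
  v <- velocity(session)
  cond <- behaviorChannel(session, "condition")
  valid <- behaviorChannel(session, "valid")
  ui <- unitInfo(session)
  M <- dff(session)
  session <- detectSessionEvents(session, config$threshold)
  ev <- sessionEvents(session)
  bouts <- S4Vectors::metadata(session)$bouts
  statsLog <- list()

  onsets <- ev[ev$event_type == "locomotion_onset", , drop = FALSE]
  eta <- NULL; respFrac <- NULL; latency <- NULL
  if (nrow(onsets) >= config$minOnsets) {
    eta <- eventTriggeredMatrix(M, onsets$frame, fr, config$window,
                                config$baseline, config$response,
                                unitData = ui)
    flags <- classifyResponsive(eta, config$alpha, config$minOnsets)
    respFrac <- responsiveFractionBySite(flags, ui$site, config$alpha)
    latency <- onsetLatency(eta, config$latencyKSd, config$latencyHold,
                            config$latencySearch, responsive = flags)
    respTest <- hierarchicalPairedTest(
      split(responseScalars(eta), ui$site), direction = "greater",
      nResamples = config$nResamples, seed = subSeed(config$seed, "resp"))
    statsLog$locomotion_onset_response <- hbootRecord(
      "locomotion onset response > 0", respTest)
  }

  boutCor <- NULL
  if (!is.null(bouts) && nrow(bouts) >= 3L) {
    boutCor <- tryCatch(
      boutResponseCorrelation(M, v, bouts, fr, minBouts = 3L),
      error = function(e) NULL)
  }

  tuning <- velocityTuningCurve(M, v, ui$site, fr, config$nVelocityBins,
                                config$velocityRange,
                                nBoot = config$nTraceResamples,
                                seed = subSeed(config$seed, "tuning"))
  binComp <- binarizationComparison(M, v, config$threshold, valid)

  pop <- colMeans(M)
  condCor <- list(
    velocity = conditionBehaviorCorrelation(pop, v, cond, valid, fr),
    pupil = conditionBehaviorCorrelation(
      pop, behaviorChannel(session, "pupil"), cond, valid, fr,
      isPupil = TRUE, minPupilSeconds = config$minPupilSeconds))

  masks <- buildStateMasks(v, fr, ev, config$threshold)
  pcStat <- meanPairwiseCorrelation(M, masks$stationary, ui$site, fr,
                                    config$minStateSeconds)
  pcLoco <- meanPairwiseCorrelation(M, masks$locomotion, ui$site, fr,
                                    config$minStateSeconds)
  pcChange <- if (nrow(pcStat) && nrow(pcLoco))
    correlationChange(pcStat, pcLoco) else NULL
  if (!is.null(pcChange) && nrow(pcChange$perUnit) > 0) {
    decorr <- hierarchicalPairedTest(
      split(pcChange$perUnit$delta_r, pcChange$perUnit$site),
      direction = "less", nResamples = config$nResamples,
      seed = subSeed(config$seed, "decorr"))
    statsLog$locomotion_decorrelation <- hbootRecord(
      "pairwise-correlation change on locomotion < 0", decorr)
  }

  report <- list(
    events = ev, bouts = bouts,
    responsive = respFrac, onset_latency_s = latency,
    eta_response = if (!is.null(eta)) responseScalars(eta) else NULL,
    bout_correlation = boutCor, velocity_tuning = tuning,
    binarization = binComp, condition_correlation = condCor,
    pairwise_stationary = pcStat, pairwise_locomotion = pcLoco,
    pairwise_change = pcChange,
    stats_log = statsLog, config = unclass(config))
  report$provenance <- list(
    seed = config$seed,
    config_hash = contentHash(unclass(config)),
    report_hash = contentHash(report))
  class(report) <- "RunReport"
  report
}

# Deterministic content hash of an R object (serialization-based; version
# 2 serialization keeps the bytes stable across R sessions). Polynomial
# rolling hash over the serialized bytes, vectorized in blocks.
contentHash <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2))
  p <- 2^31 - 1
  mult <- numeric(256)
  mult[1] <- 1
  for (k in 2:256) mult[k] <- (mult[k - 1] * 257) %% p
  h <- 0
  for (block in split(bytes, ceiling(seq_along(bytes) / 256))) {
    h <- (h * 263 + sum((block * mult[seq_along(block)]) %% p)) %% p
  }
  sprintf("%08x", h)
}

#' Write a session to a plain-text directory layout
#'
#' Serializes a [CalciumSession-class] to a directory of CSV tables
#' (traces, behavior, schedule, events, unit annotation) and a JSON
#' metadata file. Numeric fields are written as decimal text with 17
#' significant digits, so a write/read round trip is bit-identical.
#'
#' @param session a `CalciumSession`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) formatC(x, digits = 17, format = "g")
  writeMat <- function(m, file) {
    df <- as.data.frame(apply(m, c(1, 2), num), stringsAsFactors = FALSE)
    df <- cbind(unit_id = rownames(m), df)
    write.csv(df, file.path(path, file), row.names = FALSE, quote = FALSE)
  }
  for (a in SummarizedExperiment::assayNames(session))
    writeMat(SummarizedExperiment::assay(session, a),
             sprintf("traces_%s.csv", a))
  beh <- as.data.frame(SummarizedExperiment::colData(session))
  for (cc in colnames(beh))
    if (is.numeric(beh[[cc]])) beh[[cc]] <- num(beh[[cc]])
  write.csv(beh, file.path(path, "behavior.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(unitInfo(session), file.path(path, "units.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(schedule(session)))
    write.csv(schedule(session), file.path(path, "schedule.csv"),
              row.names = FALSE, quote = FALSE)
  ev <- sessionEvents(session)
  if (!is.null(ev))
    write.csv(ev, file.path(path, "events.csv"), row.names = FALSE,
              quote = FALSE)
  meta <- list(frame_rate = frameRate(session),
               n_units = nrow(session), n_frames = ncol(session),
               assays = SummarizedExperiment::assayNames(session))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from the plain-text directory layout
#'
#' @param path directory written by [writeSession()].
#' @return a [CalciumSession-class] (without generator ground truth, which
#'   is not serialized).
#' @export
readSession <- function(path) {
  metaFile <- file.path(path, "meta.json")
  if (!file.exists(metaFile))
    stop(sprintf("not a session directory (no meta.json): %s", path))
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  readMat <- function(file) {
    df <- read.csv(file.path(path, file), check.names = FALSE,
                   stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df$unit_id
    colnames(m) <- NULL
    m
  }
  beh <- read.csv(file.path(path, "behavior.csv"),
                  stringsAsFactors = FALSE)
  beh$valid <- as.logical(beh$valid)
  units <- read.csv(file.path(path, "units.csv"), stringsAsFactors = FALSE)
  sched <- if (file.exists(file.path(path, "schedule.csv")))
    read.csv(file.path(path, "schedule.csv"), stringsAsFactors = FALSE)
  else NULL
  ev <- if (file.exists(file.path(path, "events.csv")))
    read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  else NULL
  if (!is.null(ev)) {
    for (cc in c("condition", "state"))
      if (cc %in% colnames(ev)) ev[[cc]] <- as.character(ev[[cc]])
  }
  kinds <- intersect(meta$assays, c("dff", "raw"))
  first <- kinds[1]
  sess <- CalciumSession(readMat(sprintf("traces_%s.csv", first)),
                         kind = first, frameRate = as.numeric(meta$frame_rate),
                         behavior = beh, unitData = units,
                         schedule = sched, events = ev)
  for (a in setdiff(kinds, first))
    SummarizedExperiment::assay(sess, a, withDimnames = FALSE) <-
      readMat(sprintf("traces_%s.csv", a))
  sess
}
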