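#' Construct a CalciumSession
#'
#' @param traces numeric matrix, units x frames.
#' @param kind `"dff"` or `"raw"`: which assay `traces` populates.
#' @param frameRate sampling rate in Hz.
#' @param behavior data.frame with one row per frame; must contain
#'   `velocity` (cm/s) and `condition` (character); optional `flow`,
#'   `pupil`, `face`, `valid`.
#' @param unitData data.frame / DataFrame with one row per unit; must
#'   contain `mouse`, `site`, `unit_id`.
#' @param schedule data.frame of condition segments with columns
#'   `condition`, `start_frame`, `end_frame` (1-based, half-open
#'   `[start, end)` would use `end_frame + 1`; here both bounds inclusive).
#' @param events event table (see [emptyEventTable] columns), or NULL.
#' @param groundTruth list of generator ground truth, or NULL.
#'
#' @return a [CalciumSession-class] object.
#' @export
CalciumSession <- function(traces, kind = c("dff", "raw"), frameRate,
                           behavior, unitData, schedule = NULL,
                           events = NULL, groundTruth = NULL) {
  kind <- match.arg(kind)
  traces <- as.matrix(traces)
  if (nrow(behavior) != ncol(traces))
    stop("behavior must have one row per frame")
  if (!"valid" %in% colnames(behavior)) behavior$valid <- TRUE
  unitData <- S4Vectors::DataFrame(unitData)
  if (nrow(unitData) != nrow(traces))
    stop("unitData must have one row per unit")
  rownames(traces) <- unitData$unit_id
  assays <- stats::setNames(list(traces), kind)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = unitData,
    colData = S4Vectors::DataFrame(behavior),
    metadata = list(schedule = schedule,
                    events = if (is.null(events)) emptyEventTable() else events,
                    ground_truth = groundTruth))
  new("CalciumSession", se, frameRate = frameRate)
}

#' Accessors for CalciumSession objects
#'
#' `frameRate` returns the sampling rate (Hz); `dff` / `rawF` the trace
#' matrices; `velocity` and `behaviorChannel` the frame-wise behavior
#' channels; `schedule` the condition-segment table; `sessionEvents` the
#' event table; `groundTruth` the generator ground truth (synthetic
#' sessions); `unitInfo` the unit annotation as a data.frame.
#'
#' @param x a `CalciumSession`.
#' @param channel behavior column name, e.g. `"velocity"`, `"pupil"`.
#' @param value replacement event table.
#' @name CalciumSession-accessors
NULL

#' @rdname CalciumSession-accessors
#' @export
setMethod("frameRate", "CalciumSession", function(x) x@frameRate)

#' @rdname CalciumSession-accessors
#' @export
setMethod("dff", "CalciumSession", function(x) {
  if (!"dff" %in% SummarizedExperiment::assayNames(x))
    stop("session has no 'dff' assay; run computeDFF() first")
  SummarizedExperiment::assay(x, "dff")
})

#' @rdname CalciumSession-accessors
#' @export
setMethod("rawF", "CalciumSession", function(x) {
  if (!"raw" %in% SummarizedExperiment::assayNames(x))
    stop("session has no 'raw' assay")
  SummarizedExperiment::assay(x, "raw")
})

#' @rdname CalciumSession-accessors
#' @export
setMethod("behaviorChannel", "CalciumSession", function(x, channel) {
  cd <- SummarizedExperiment::colData(x)
  if (!channel %in% colnames(cd))
    stop(sprintf("no behavior channel '%s'", channel))
  cd[[channel]]
})

#' @rdname CalciumSession-accessors
#' @export
setMethod("velocity", "CalciumSession",
          function(x) behaviorChannel(x, "velocity"))

#' @rdname CalciumSession-accessors
#' @export
setMethod("schedule", "CalciumSession",
          function(x) S4Vectors::metadata(x)$schedule)

#' @rdname CalciumSession-accessors
#' @export
setMethod("sessionEvents", "CalciumSession",
          function(x) S4Vectors::metadata(x)$events)

#' @rdname CalciumSession-accessors
#' @export
setMethod("sessionEvents<-", "CalciumSession", function(x, value) {
  S4Vectors::metadata(x)$events <- value
  x
})

#' @rdname CalciumSession-accessors
#' @export
setMethod("groundTruth", "CalciumSession",
          function(x) S4Vectors::metadata(x)$ground_truth)

#' @rdname CalciumSession-accessors
#' @export
setMethod("unitInfo", "CalciumSession", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

setMethod("show", "CalciumSession", function(object) {
  cat(sprintf("CalciumSession: %d units x %d frames at %g Hz (%.1f min)\n",
              nrow(object), ncol(object), object@frameRate,
              ncol(object) / object@frameRate / 60))
  ui <- SummarizedExperiment::rowData(object)
  cat(sprintf("  mice: %d  sites: %d  assays: %s\n",
              length(unique(ui$mouse)),
              length(unique(paste(ui$mouse, ui$site))),
              paste(SummarizedExperiment::assayNames(object),
                    collapse = ", ")))
  sched <- schedule(object)
  if (!is.null(sched))
    cat(sprintf("  conditions: %s\n",
                paste(unique(sched$condition), collapse = ", ")))
  ev <- sessionEvents(object)
  if (!is.null(ev) && nrow(ev) > 0)
    cat(sprintf("  events: %d (%s)\n", nrow(ev),
                paste(unique(ev$event_type), collapse = ", ")))
  invisible(NULL)
})

#' Accessors for ETAResult objects
#'
#' @param x an `ETAResult`.
#' @name ETAResult-accessors
NULL

#' @rdname ETAResult-accessors
#' @export
setMethod("meanTrace", "ETAResult", function(x) x@meanTrace)

#' @rdname ETAResult-accessors
#' @export
setMethod("responseScalars", "ETAResult", function(x) x@response)

#' @rdname ETAResult-accessors
#' @export
setMethod("snippetTime", "ETAResult", function(x) x@time)

#' @rdname ETAResult-accessors
#' @export
setMethod("nOnsets", "ETAResult", function(x) x@nOnsets)

setMethod("show", "ETAResult", function(object) {
  d <- dim(object@snippets)
  cat(sprintf(paste0("ETAResult: %d units x %d events, window [%g, %g) s,",
                     " baseline [%g, %g) s, response [%g, %g) s\n"),
              d[1], d[2], object@window[1], object@window[2],
              object@baselineWindow[1], object@baselineWindow[2],
              object@responseWindow[1], object@responseWindow[2]))
  invisible(NULL)
})

#' Accessors for HBootResult objects
#'
#' `bootMeans` returns the replicate means, `bootCI` the 95 percent
#' percentile interval, and `pValue` the one- or two-sided bootstrap p value
#' (the one-sided p is the proportion of replicate means on the null side of
#' zero for the stored direction; ties at exactly zero count toward the
#' null).
#'
#' @param x an `HBootResult`.
#' @param alternative `"one.sided"` (stored direction) or `"two.sided"`.
#' @name HBootResult-accessors
NULL

#' @rdname HBootResult-accessors
#' @export
setMethod("bootMeans", "HBootResult", function(x) x@bootMeans)

#' @rdname HBootResult-accessors
#' @export
setMethod("bootCI", "HBootResult", function(x) x@ci)

#' @rdname HBootResult-accessors
#' @export
setMethod("pValue", "HBootResult",
          function(x, alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (alternative == "two.sided")
    return(min(1, 2 * min(x@pLow, x@pHigh)))
  switch(x@direction,
         greater = x@pLow,
         less = x@pHigh,
         stop("stored direction must be 'greater' or 'less'"))
})

setMethod("show", "HBootResult", function(object) {
  cat(sprintf(paste0("HBootResult: estimate %.4g, 95%% CI [%.4g, %.4g], ",
                     "p(%s) = %.4g (two-sided %.4g), %d resamples\n"),
              object@estimate, object@ci[1], object@ci[2], object@direction,
              pValue(object), pValue(object, "two.sided"),
              object@nResamples))
  cat(sprintf("  nesting: %s\n", object@nesting))
  invisible(NULL)
})
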