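#' CalciumSession: one imaging session with behavior on a shared clock
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment].
#' Rows are units (axons or neurons, nested in imaging sites, nested in
#' mice), columns are imaging frames at a single frame rate. Assays hold the
#' unit x frame trace matrices (`"raw"` fluorescence and/or `"dff"`),
#' `rowData` carries the unit nesting ids (`mouse`, `site`, `unit_id`) plus
#' any ground-truth unit annotation, and `colData` carries the frame-wise
#' behavior channels (`velocity` in cm/s, `flow`, `pupil`, `face`, logical
#' `valid`) and the `condition` label of each frame. `metadata()` stores the
#' frame rate, the condition schedule, the event table and (for synthetic
#' sessions) the generator ground truth.
#'
#' @slot frameRate sampling rate in Hz (canonically 15).
#' @export
setClass("CalciumSession",
         contains = "SummarizedExperiment",
         slots = c(frameRate = "numeric"))

setValidity("CalciumSession", function(object) {
  msg <- character(0)
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(SummarizedExperiment::assayNames(object)) == 0L)
    msg <- c(msg, "at least one assay ('raw' or 'dff') is required")
  for (a in SummarizedExperiment::assayNames(object)) {
    if (anyNA(SummarizedExperiment::assay(object, a)))
      msg <- c(msg, sprintf("assay '%s' contains NA/NaN values", a))
  }
  cd <- SummarizedExperiment::colData(object)
  for (col in c("velocity", "condition")) {
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain a '%s' column", col))
  }
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("mouse", "site", "unit_id")) {
    if (!col %in% colnames(rd))
      msg <- c(msg, sprintf("rowData must contain a '%s' column", col))
  }
  if (length(msg)) msg else TRUE
})

#' ETAResult: event-triggered response matrices for a unit population
#'
#' Holds, for one event class, the per-unit snippet matrices (unit x event x
#' time), the baseline-subtracted mean traces, the per-event baseline and
#' response-window means used by the responsiveness test, and the per-unit
#' baseline-subtracted response scalar.
#'
#' @slot snippets three-dimensional array unit x event x time of dF/F.
#' @slot time numeric vector of snippet times in seconds relative to the
#'   event (t = 0 at the event frame).
#' @slot window,baselineWindow,responseWindow numeric length-2 windows in
#'   seconds, half-open `[start, end)`.
#' @slot meanTrace matrix unit x time: mean over events, baseline-subtracted.
#' @slot baselineMeans,responseMeans matrices unit x event of per-event
#'   window means (not baseline-subtracted).
#' @slot response numeric per-unit scalar: mean over events of
#'   (response-window mean - baseline mean).
#' @slot nOnsets integer per-unit number of events entering the average.
#' @slot unitData DataFrame of unit annotation (mouse, site, unit_id, ...).
#' @slot frameRate sampling rate in Hz.
#' @export
setClass("ETAResult",
         slots = c(snippets = "array", time = "numeric", window = "numeric",
                   baselineWindow = "numeric", responseWindow = "numeric",
                   meanTrace = "matrix", baselineMeans = "matrix",
                   responseMeans = "matrix", response = "numeric",
                   nOnsets = "integer", unitData = "DataFrame",
                   frameRate = "numeric"))

setValidity("ETAResult", function(object) {
  msg <- character(0)
  d <- dim(object@snippets)
  if (length(d) != 3L) msg <- c(msg, "snippets must be unit x event x time")
  if (length(object@time) != d[3]) msg <- c(msg, "time axis length mismatch")
  if (!all(diff(object@time) > 0)) msg <- c(msg, "time must be increasing")
  if (any(object@nOnsets < 0L)) msg <- c(msg, "negative onset count")
  if (length(msg)) msg else TRUE
})

#' HBootResult: nested hierarchical bootstrap summary
#'
#' Result of resampling imaging sites with replacement and then, within each
#' drawn site, resampling its units with replacement; the grand mean over the
#' drawn values is recorded per replicate.
#'
#' @slot estimate grand mean of the original data.
#' @slot bootMeans numeric vector of replicate means.
#' @slot ci numeric length-2, 2.5/97.5 percentiles of `bootMeans`.
#' @slot pLow,pHigh proportions of replicate means `<= 0` / `>= 0` (paired
#'   tests) or of misordered replicate pairs (unpaired tests).
#' @slot direction alternative hypothesis the one-sided p refers to.
#' @slot nResamples number of bootstrap replicates.
#' @slot seed integer seed used, or NA.
#' @slot nesting text description of the resampling hierarchy.
#' @export
setClass("HBootResult",
         slots = c(estimate = "numeric", bootMeans = "numeric",
                   ci = "numeric", pLow = "numeric", pHigh = "numeric",
                   direction = "character", nResamples = "integer",
                   seed = "integer", nesting = "character"))

setValidity("HBootResult", function(object) {
  msg <- character(0)
  if (object@pLow < 0 || object@pLow > 1 ||
      object@pHigh < 0 || object@pHigh > 1)
    msg <- c(msg, "p values must lie in [0, 1]")
  if (length(object@ci) != 2L || any(is.na(object@ci)))
    msg <- c(msg, "ci must be two finite numbers")
  if (object@ci[1] > median(object@bootMeans) ||
      object@ci[2] < median(object@bootMeans))
    msg <- c(msg, "ci must contain the bootstrap median")
  if (length(msg)) msg else TRUE
})
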