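# State- and condition-resolved mean pairwise correlation analysis.

#' Build named frame masks by locomotion state and manipulation
#'
#' Splits the session frames by the binarized locomotion state and the
#' presence of optogenetic stimulation: `stationary` and `locomotion`
#' exclude opto frames, `opto_stationary` / `opto_locomotion` cover them.
#' The masks are mutually exclusive and jointly cover all frames.
#'
#' @param velocityTrace velocity (cm/s).
#' @param frameRate sampling rate (Hz).
#' @param optoEvents optional event table of `opto_onset` events with a
#'   `duration` column (s).
#' @param threshold locomotion threshold (cm/s).
#' @return named list of logical frame masks.
#' @export
buildStateMasks <- function(velocityTrace, frameRate, optoEvents = NULL,
                            threshold = 0.25) {
  n <- length(velocityTrace)
  loco <- velocityTrace >= threshold
  opto <- rep(FALSE, n)
  if (!is.null(optoEvents) && nrow(optoEvents) > 0) {
    ev <- optoEvents[optoEvents$event_type == "opto_onset", , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      f0 <- ev$frame[k]
      f1 <- min(n, f0 + secToFrames(ev$duration[k] %||% 1, frameRate) - 1L)
      opto[f0:f1] <- TRUE
    }
  }
  list(stationary = !loco & !opto,
       locomotion = loco & !opto,
       opto_stationary = !loco & opto,
       opto_locomotion = loco & opto)
}

#' Mean pairwise correlation per unit under a frame mask
#'
#' For every imaging site with at least two units and at least
#' `minDuration` seconds of masked frames, computes the Pearson
#' correlation of every unordered same-site unit pair over the masked
#' frames and averages, for each unit, its correlations with all other
#' units of the site. Sites below the duration threshold are excluded
#' (with a message); zero-variance units yield undefined pairs that are
#' excluded from the means.
#'
#' @param traces unit x frame dF/F matrix.
#' @param mask logical frame mask.
#' @param sites site label per unit.
#' @param frameRate sampling rate (Hz).
#' @param minDuration minimum masked duration (s) for a site.
#' @return data.frame: `unit_id`, `site`, `mean_r`, `n_pairs`,
#'   `n_frames`; units of excluded sites are absent.
#' @export
meanPairwiseCorrelation <- function(traces, mask, sites, frameRate,
                                    minDuration = 15) {
  traces <- as.matrix(traces)
  nFrames <- sum(mask)
  out <- NULL
  for (s in unique(sites)) {
    rows <- which(sites == s)
    if (length(rows) < 2L) next
    if (nFrames / frameRate < minDuration) {
      message(sprintf(
        "meanPairwiseCorrelation: site %s excluded (%.1f s < %g s)",
        s, nFrames / frameRate, minDuration))
      next
    }
    M <- traces[rows, mask, drop = FALSE]
    sds <- apply(M, 1, sd)
    C <- suppressWarnings(cor(t(M)))
    C[sds == 0, ] <- NA; C[, sds == 0] <- NA
    diag(C) <- NA
    out <- rbind(out, data.frame(
      unit_id = rownames(M) %||% paste0(s, "_", seq_along(rows)),
      site = s,
      mean_r = rowMeans(C, na.rm = TRUE),
      n_pairs = rowSums(!is.na(C)),
      n_frames = nFrames, stringsAsFactors = FALSE))
  }
  if (is.null(out)) out <- data.frame(unit_id = character(0),
                                      site = character(0),
                                      mean_r = numeric(0),
                                      n_pairs = integer(0),
                                      n_frames = integer(0))
  out$mean_r[out$n_pairs == 0L] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Change in mean pairwise correlation between two conditions
#'
#' Per-unit difference `mean_r(B) - mean_r(A)` over units present in both
#' results, with a per-site summary.
#'
#' @param resultA,resultB results of [meanPairwiseCorrelation()] under two
#'   masks (A = reference, e.g. stationary).
#' @return list with `perUnit` (unit_id, site, delta_r) and `perSite`
#'   (site, mean_delta, n_units).
#' @export
correlationChange <- function(resultA, resultB) {
  common <- intersect(resultA$unit_id, resultB$unit_id)
  a <- resultA[match(common, resultA$unit_id), ]
  b <- resultB[match(common, resultB$unit_id), ]
  perUnit <- data.frame(unit_id = common, site = a$site,
                        delta_r = b$mean_r - a$mean_r,
                        stringsAsFactors = FALSE)
  agg <- stats::aggregate(delta_r ~ site, perUnit, mean)
  cnt <- stats::aggregate(delta_r ~ site, perUnit, length)
  perSite <- data.frame(site = agg$site, mean_delta = agg$delta_r,
                        n_units = cnt$delta_r)
  list(perUnit = perUnit, perSite = perSite)
}

# All unordered same-site pair correlations under a mask.
pairwiseCorrelations <- function(traces, mask, sites) {
  traces <- as.matrix(traces)
  out <- NULL
  for (s in unique(sites)) {
    rows <- which(sites == s)
    if (length(rows) < 2L) next
    M <- traces[rows, mask, drop = FALSE]
    C <- suppressWarnings(cor(t(M)))
    ut <- which(upper.tri(C), arr.ind = TRUE)
    out <- rbind(out, data.frame(site = s,
                                 i = rows[ut[, 1]], j = rows[ut[, 2]],
                                 r = C[ut]))
  }
  out
}

#' Pairwise-correlation change stratified by baseline correlation
#'
#' Computes pair-level correlations under a reference mask (stationary)
#' and a comparison mask (locomotion), bins the pairs by their reference
#' correlation into quantile bins, and returns the mean
#' comparison-minus-reference difference per bin. Reveals whether weakly
#' correlated pairs decorrelate while strongly correlated pairs increase
#' their coupling.
#'
#' @param traces unit x frame dF/F matrix.
#' @param maskRef,maskCmp logical frame masks (reference / comparison).
#' @param sites site label per unit.
#' @param nBins number of quantile bins on the reference correlation.
#' @return data.frame: `bin`, `r_ref_lo`, `r_ref_hi`, `n_pairs`,
#'   `mean_delta` (NA for empty bins).
#' @export
correlationByBaselineQuantile <- function(traces, maskRef, maskCmp, sites,
                                          nBins = 5L) {
  ref <- pairwiseCorrelations(traces, maskRef, sites)
  cmp <- pairwiseCorrelations(traces, maskCmp, sites)
  if (is.null(ref) || is.null(cmp)) stop("no unit pairs available")
  key <- function(d) paste(d$site, d$i, d$j)
  m <- match(key(ref), key(cmp))
  ok <- !is.na(m) & is.finite(ref$r)
  delta <- cmp$r[m[ok]] - ref$r[ok]
  rref <- ref$r[ok]
  qs <- quantile(rref, probs = seq(0, 1, length.out = nBins + 1L))
  bin <- cut(rref, breaks = unique(qs), include.lowest = TRUE)
  lev <- levels(bin)
  data.frame(bin = seq_along(lev),
             r_ref_lo = head(qs, -1)[seq_along(lev)],
             r_ref_hi = tail(qs, -1)[seq_along(lev)],
             n_pairs = as.integer(table(bin)),
             mean_delta = as.numeric(tapply(delta, bin, mean)))
}
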