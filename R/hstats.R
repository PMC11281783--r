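# Nested hierarchical bootstrap and KS-gated classical tests.

# Normalize input to a named list of numeric per-site value vectors.
asSiteList <- function(values, sites = NULL) {
  if (is.list(values)) {
    vals <- lapply(values, as.numeric)
  } else {
    if (is.null(sites)) stop("sites must be given with a flat value vector")
    vals <- split(as.numeric(values), sites)
  }
  vals <- vals[vapply(vals, length, integer(1)) > 0]
  if (length(vals) == 0L) stop("no sites with values")
  vals
}

# Core resampler: sites with replacement, then values within each drawn
# site with replacement (each drawn site contributes its own value count);
# returns the vector of replicate grand means over the pooled drawn values.
hbootReplicates <- function(siteList, nResamples) {
  S <- length(siteList)
  sizes <- vapply(siteList, length, integer(1))
  if (length(unique(sizes)) == 1L) {
    # equal site sizes: fully vectorized
    m <- sizes[1]
    flat <- unlist(siteList, use.names = FALSE)
    siteDraw <- sample.int(S, nResamples * S, replace = TRUE)
    offs <- rep((siteDraw - 1L) * m, each = m)
    valDraw <- sample.int(m, nResamples * S * m, replace = TRUE)
    v <- flat[offs + valDraw]
    rowMeans(matrix(v, nrow = nResamples, byrow = TRUE))
  } else {
    vapply(seq_len(nResamples), function(r) {
      ss <- sample.int(S, S, replace = TRUE)
      tot <- 0; cnt <- 0L
      for (s in ss) {
        x <- siteList[[s]]
        d <- x[sample.int(length(x), length(x), replace = TRUE)]
        tot <- tot + sum(d); cnt <- cnt + length(d)
      }
      tot / cnt
    }, numeric(1))
  }
}

hbootResult <- function(siteList, boot, direction, nResamples, seed,
                        nesting) {
  est <- mean(unlist(siteList, use.names = FALSE))
  new("HBootResult", estimate = est, bootMeans = boot,
      ci = unname(quantile(boot, c(0.025, 0.975), type = 7)),
      pLow = mean(boot <= 0), pHigh = mean(boot >= 0),
      direction = direction, nResamples = as.integer(nResamples),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nesting = nesting)
}

#' Nested hierarchical bootstrap of a mean
#'
#' Resamples imaging sites with replacement (keeping the site count), then
#' within every drawn site resamples its values (axons/neurons/pairs) with
#' replacement (keeping that site's value count), and records the grand
#' mean over the pooled drawn values; repeated `nResamples` times.
#'
#' @param values a list of per-site numeric vectors, or a flat numeric
#'   vector accompanied by `sites`.
#' @param sites site label per value when `values` is flat.
#' @param nResamples number of bootstrap replicates (10000 in the standard
#'   analyses, 1000 for trace-bin comparisons).
#' @param seed optional RNG seed; stored in the result.
#' @param direction alternative for the one-sided p (`"greater"`: p is the
#'   proportion of replicate means at or below zero).
#' @return an [HBootResult-class].
#' @export
hierarchicalBootstrapMean <- function(values, sites = NULL,
                                      nResamples = 10000L, seed = NULL,
                                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  siteList <- asSiteList(values, sites)
  boot <- withSeed(seed, hbootReplicates(siteList, nResamples))
  hbootResult(siteList, boot, direction, nResamples, seed,
              sprintf("sites (%d) -> values", length(siteList)))
}

#' Hierarchical paired test on nested differences
#'
#' Bootstraps the mean of per-unit paired differences with the nested
#' site -> unit scheme; the one-sided p value is the proportion of
#' replicate means on the null side of zero for the stated direction (ties
#' at zero count toward the null), and the two-sided p is
#' `min(1, 2 * min(pLow, pHigh))`.
#'
#' @param differences list of per-site vectors of paired differences, or a
#'   flat vector with `sites`.
#' @inheritParams hierarchicalBootstrapMean
#' @return an [HBootResult-class].
#' @export
hierarchicalPairedTest <- function(differences, sites = NULL,
                                   direction = c("greater", "less"),
                                   nResamples = 10000L, seed = NULL) {
  direction <- match.arg(direction)
  hierarchicalBootstrapMean(differences, sites, nResamples, seed, direction)
}

#' Hierarchical unpaired test between two nested samples
#'
#' Independently bootstraps the mean of each sample with the nested scheme
#' and compares the replicate pairs: for `direction = "greater"` (A > B)
#' the one-sided p is the proportion of replicates with
#' `mean_A <= mean_B`.
#'
#' @param valuesA,valuesB per-site value lists (or flat vectors with
#'   `sitesA` / `sitesB`).
#' @param sitesA,sitesB site labels for flat input.
#' @inheritParams hierarchicalBootstrapMean
#' @return an [HBootResult-class]; `estimate` is `mean(A) - mean(B)` and
#'   `bootMeans` the replicate differences.
#' @export
hierarchicalUnpairedTest <- function(valuesA, valuesB, sitesA = NULL,
                                     sitesB = NULL,
                                     direction = c("greater", "less"),
                                     nResamples = 10000L, seed = NULL) {
  direction <- match.arg(direction)
  la <- asSiteList(valuesA, sitesA)
  lb <- asSiteList(valuesB, sitesB)
  boots <- withSeed(seed, {
    ba <- hbootReplicates(la, nResamples)
    bb <- hbootReplicates(lb, nResamples)
    list(ba = ba, bb = bb)
  })
  d <- boots$ba - boots$bb
  res <- hbootResult(list(0), d, direction, nResamples, seed,
                     sprintf("A: sites (%d) -> values; B: sites (%d) -> values",
                             length(la), length(lb)))
  res@estimate <- mean(unlist(la)) - mean(unlist(lb))
  res
}

#' Bin-by-bin comparison of response traces
#'
#' Compares two unit x time response matrices per time bin with the nested
#' hierarchical bootstrap (paired when the matrices share units, unpaired
#' otherwise), using one resampling of the unit hierarchy per replicate
#' applied to all bins. Bins with p < `alpha` are flagged; no
#' multiple-comparison correction is applied, and this is recorded in the
#' result.
#'
#' @param tracesA,tracesB unit x time matrices.
#' @param sitesA,sitesB site label per unit (row).
#' @param paired TRUE when rows of A and B are the same units.
#' @param nResamples bootstrap replicates (default 1000 for traces).
#' @param alpha significance level per bin.
#' @param seed optional RNG seed.
#' @return list with `p` (per-bin two-sided p), `significant` (logical
#'   mask), `estimate` (per-bin mean difference), `correction = "none"`.
#' @export
binwiseTraceComparison <- function(tracesA, tracesB, sitesA,
                                   sitesB = sitesA, paired = TRUE,
                                   nResamples = 1000L, alpha = 0.05,
                                   seed = NULL) {
  withSeed(seed, {
    if (paired) {
      stopifnot(nrow(tracesA) == nrow(tracesB))
      D <- tracesA - tracesB
      boot <- hbootTraceReplicates(D, sitesA, nResamples)
      est <- colMeans(D)
    } else {
      ba <- hbootTraceReplicates(tracesA, sitesA, nResamples)
      bb <- hbootTraceReplicates(tracesB, sitesB, nResamples)
      boot <- ba - bb
      est <- colMeans(tracesA) - colMeans(tracesB)
    }
    pLow <- colMeans(boot <= 0)
    pHigh <- colMeans(boot >= 0)
    p <- pmin(1, 2 * pmin(pLow, pHigh))
    list(p = p, significant = p < alpha, estimate = est,
         correction = "none", nResamples = nResamples)
  })
}

# One nested resample of rows per replicate, mean trace per replicate:
# returns nResamples x time matrix.
hbootTraceReplicates <- function(M, sites, nResamples) {
  bySite <- split(seq_len(nrow(M)), sites)
  S <- length(bySite)
  t(vapply(seq_len(nResamples), function(r) {
    ss <- sample.int(S, S, replace = TRUE)
    rows <- unlist(lapply(bySite[ss], function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    colMeans(M[rows, , drop = FALSE])
  }, numeric(ncol(M))))
}

#' Classical site-level test with a normality gate
#'
#' For analyses whose experimental unit is the imaging site: the analysis
#' values are first tested for normality with a Kolmogorov-Smirnov test of
#' the z-scored values against the standard normal at the 5 percent level
#' (note: z-scoring estimates the parameters, so the gate is the Lilliefors
#' statistic evaluated against the plain KS reference). If the gate passes,
#' means are compared with a paired or unpaired t-test; otherwise medians
#' are compared with the Wilcoxon signed-rank (paired) or rank-sum
#' (unpaired) test.
#'
#' @param x numeric values (first group, or paired first measurement).
#' @param y second group / measurement, or NULL for a one-sample test
#'   against zero.
#' @param paired TRUE for paired comparisons.
#' @param alphaNorm significance level of the normality gate.
#' @return list with `test` (name), `statistic`, `p.value`, `normal`
#'   (gate outcome).
#' @export
classicalSiteTest <- function(x, y = NULL, paired = FALSE,
                              alphaNorm = 0.05) {
  ksNormal <- function(v) {
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    z <- (v - mean(v)) / sd(v)
    suppressWarnings(ks.test(z, "pnorm")$p.value) >= alphaNorm
  }
  if (paired || is.null(y)) {
    d <- if (is.null(y)) x else x - y
    if (all(d == 0))
      return(list(test = "degenerate (all differences zero)",
                  statistic = NA_real_, p.value = 1, normal = NA))
    normal <- ksNormal(d)
    if (normal) {
      tt <- t.test(d)
      list(test = "paired t-test", statistic = unname(tt$statistic),
           p.value = tt$p.value, normal = TRUE)
    } else {
      wt <- suppressWarnings(wilcox.test(d))
      list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
           p.value = wt$p.value, normal = FALSE)
    }
  } else {
    normal <- ksNormal(x) && ksNormal(y)
    if (normal) {
      tt <- t.test(x, y)
      list(test = "unpaired t-test", statistic = unname(tt$statistic),
           p.value = tt$p.value, normal = TRUE)
    } else {
      wt <- suppressWarnings(wilcox.test(x, y))
      list(test = "Wilcoxon rank-sum", statistic = unname(wt$statistic),
           p.value = wt$p.value, normal = FALSE)
    }
  }
}

# JSON-able record of a bootstrap test, for the run-level statistics log.
hbootRecord <- function(name, res) {
  list(test = name, estimate = res@estimate, ci = res@ci,
       p_one_sided = pValue(res), p_two_sided = pValue(res, "two.sided"),
       direction = res@direction, n_resamples = res@nResamples,
       seed = res@seed, nesting = res@nesting)
}
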