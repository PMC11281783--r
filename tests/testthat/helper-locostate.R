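# Shared fixtures and independent brute-force oracles.

# Small, fast generator configuration for structural tests.
tinyConfig <- function(...) {
  args <- list(nMice = 1L, sitesPerMouse = 2L, unitsPerSite = 6L,
               conditionDurations = c(closed_loop = 240, open_loop = 120,
                                      grating = 120, dark = 120),
               boutRate = 1.5, boutDurationMeanLog = log(12),
               boutDurationSdLog = 0.4, boutDurationMin = 4,
               boutDurationMax = 25, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthConfig, args)
}

# Brute-force onset scanner: frame-by-frame application of the rule
# "v >= th on all of [f, f+hold) and v < th on all of [f-quiet, f)".
bruteOnsets <- function(v, th, holdF, quietF, edgeLo = NULL, edgeHi = NULL) {
  n <- length(v)
  out <- integer(0)
  for (f in seq_len(n)) {
    if (f - quietF < 1L || f + holdF - 1L > n) next
    if (all(v[f:(f + holdF - 1L)] >= th) &&
        all(v[(f - quietF):(f - 1L)] < th)) out <- c(out, f)
  }
  if (!is.null(edgeLo))
    out <- out[out + edgeLo >= 1L & out + edgeHi - 1L <= n]
  out
}

bruteOffsets <- function(v, th, holdF, priorF, edgeLo = NULL, edgeHi = NULL) {
  n <- length(v)
  out <- integer(0)
  for (f in seq_len(n)) {
    if (f - priorF < 1L || f + holdF - 1L > n) next
    if (all(v[f:(f + holdF - 1L)] < th) &&
        all(v[(f - priorF):(f - 1L)] >= th)) out <- c(out, f)
  }
  if (!is.null(edgeLo))
    out <- out[out + edgeLo >= 1L & out + edgeHi - 1L <= n]
  out
}

# Brute-force rolling percentile baseline (per-frame full quantile).
bruteRollQuantile <- function(x, left, right, p) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - left):min(n, i + right)
    unname(quantile(x[w], p, type = 7))
  }, numeric(1))
}

# Random velocity traces exercising threshold edge cases.
randomVelocity <- function(n, frameRate = 15) {
  v <- abs(stats::filter(rnorm(n, 0, 0.4), rep(1 / 4, 4),
                         method = "convolution", sides = 1))
  v[is.na(v)] <- 0
  # mix in plateaus and exact-threshold values
  k <- sample(n - 20, 3)
  for (f in k) v[f:(f + sample(5:20, 1))] <- sample(c(0, 0.25, 0.3, 1), 1)
  as.numeric(v)
}
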