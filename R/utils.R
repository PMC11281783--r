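# Shared helpers: frame/time conversions, window arithmetic, RNG substreams.

#' Convert a time in seconds to a whole number of frames
#'
#' Uses `round()` (half-to-even), the single conversion rule applied
#' throughout the package so that all analyses agree on window extents.
#'
#' @param seconds numeric vector of durations or offsets in seconds.
#' @param frameRate sampling rate in Hz.
#' @return integer vector of frame counts/offsets.
#' @export
secToFrames <- function(seconds, frameRate) {
  as.integer(round(seconds * frameRate))
}

# Frame indices (1-based) covered by a half-open window [w1, w2) in seconds
# relative to an event frame. Returns integer(0) if the window leaves the
# recording [1, nFrames].
windowFrames <- function(eventFrame, window, frameRate, nFrames) {
  lo <- eventFrame + secToFrames(window[1], frameRate)
  hi <- eventFrame + secToFrames(window[2], frameRate) - 1L
  if (lo < 1L || hi > nFrames || hi < lo) return(integer(0))
  seq.int(lo, hi)
}

# Relative frame offsets of a half-open window [w1, w2) in seconds.
windowOffsets <- function(window, frameRate) {
  seq.int(secToFrames(window[1], frameRate),
          secToFrames(window[2], frameRate) - 1L)
}

# Derive a reproducible integer sub-seed (< 2^31) from a root seed and a
# stream label, so that generator stages can be re-run independently.
subSeed <- function(seed, stream) {
  chars <- utf8ToInt(stream)
  h <- (sum(chars * seq_along(chars)) * 2654435761) %% 1e9
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards (a local, dependency-free withr::with_seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# AR(1) series of length n with unit marginal variance, innovation-driven.
ar1Unit <- function(n, phi) {
  if (n == 0L) return(numeric(0))
  innov <- rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Mixed AR(1) + white noise with unit total variance; `arShare` is the
# variance fraction carried by the slow AR component.
slowNoise <- function(n, phi, arShare = 0.7) {
  sqrt(arShare) * ar1Unit(n, phi) + sqrt(1 - arShare) * rnorm(n)
}

# Causal exponential low-pass with time constant tau (s); unit DC gain.
expSmooth <- function(x, tau, frameRate) {
  if (tau <= 0) return(x)
  alpha <- 1 - exp(-1 / (tau * frameRate))
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive"))
}

# An empty event table with the canonical column set.
emptyEventTable <- function() {
  data.frame(event_type = character(0), frame = integer(0),
             time_s = numeric(0), condition = character(0),
             state = character(0), orientation = numeric(0),
             duration = numeric(0), stringsAsFactors = FALSE)
}

# Assemble an event table row block; recycles scalar metadata.
makeEventTable <- function(event_type, frame, frameRate,
                           condition = NA_character_, state = NA_character_,
                           orientation = NA_real_, duration = NA_real_) {
  n <- length(frame)
  if (n == 0L) return(emptyEventTable())
  out <- data.frame(event_type = rep_len(event_type, n),
                    frame = as.integer(frame),
                    time_s = (as.integer(frame) - 1L) / frameRate,
                    condition = rep_len(condition, n),
                    state = rep_len(state, n),
                    orientation = rep_len(orientation, n),
                    duration = rep_len(duration, n),
                    stringsAsFactors = FALSE)
  out[order(out$frame), , drop = FALSE]
}

# rbind event tables (any may be empty / NULL), keeping frame order.
bindEventTables <- function(...) {
  tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(tabs) == 0L) return(emptyEventTable())
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out[order(out$frame), , drop = FALSE]
}
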