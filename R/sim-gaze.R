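#' Simulate a gaze trace realizing a schedule's ocular events
#'
#' Produces piecewise-constant fixations joined by smooth saccadic ramps
#' of the scheduled magnitudes (random directions, position reflected
#' back into the stimulus area when a step would leave it), with blink
#' intervals marked invalid. Units are visual degrees relative to screen
#' center.
#'
#' @param schedule event tibble; only `saccade_*` and `blink` rows are
#'   used.
#' @param fs gaze sampling rate, Hz (the tracker's 500 Hz by default).
#' @param duration_ms trace length; defaults to the schedule's.
#' @param bounds_deg half-extent of the area gaze may occupy, degrees.
#' @param seed seed for saccade directions.
#' @return a `gaze_trace` tibble with columns `time_ms`, `x_deg`,
#'   `y_deg`, `valid`, plus an `fs` attribute.
#' @export
simulate_gaze <- function(schedule, fs = 500, duration_ms = NULL,
                          bounds_deg = 6, seed = NULL) {
  if (is.null(duration_ms)) duration_ms <- attr(schedule, "duration_ms")
  if (is.null(duration_ms)) duration_ms <- max(schedule$offset_ms) + 100
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_ms / 1000 * fs)
  time_ms <- (seq_len(n) - 1) / fs * 1000
  sacc <- schedule[startsWith(schedule$condition, "saccade"), ]
  sacc <- sacc[order(sacc$onset_ms), ]
  if (nrow(sacc) > 1 &&
      any(sacc$onset_ms[-1] < sacc$offset_ms[-nrow(sacc)]))
    stop("overlapping saccade intervals in schedule", call. = FALSE)
  x <- numeric(n); y <- numeric(n)
  pos <- c(0, 0)
  cursor <- 1L
  for (i in seq_len(nrow(sacc))) {
    i0 <- min(n, round(sacc$onset_ms[i] / 1000 * fs) + 1L)
    i1 <- min(n, round(sacc$offset_ms[i] / 1000 * fs) + 1L)
    if (i1 <= i0) next
    x[cursor:i0] <- pos[1]; y[cursor:i0] <- pos[2]
    target <- saccade_target(pos, sacc$magnitude_deg[i], bounds_deg)
    # raised-cosine ramp preserves the end-to-end displacement magnitude
    frac <- (1 - cos(pi * seq(0, 1, length.out = i1 - i0 + 1))) / 2
    x[i0:i1] <- pos[1] + frac * (target[1] - pos[1])
    y[i0:i1] <- pos[2] + frac * (target[2] - pos[2])
    pos <- target
    cursor <- i1
  }
  x[cursor:n] <- pos[1]; y[cursor:n] <- pos[2]
  valid <- rep(TRUE, n)
  bl <- schedule[schedule$condition == "blink", ]
  for (i in seq_len(nrow(bl))) {
    j0 <- max(1L, round(bl$onset_ms[i] / 1000 * fs) + 1L)
    j1 <- min(n, round(bl$offset_ms[i] / 1000 * fs) + 1L)
    if (j1 >= j0) valid[j0:j1] <- FALSE
  }
  out <- tibble::tibble(time_ms = time_ms, x_deg = x, y_deg = y,
                        valid = valid)
  attr(out, "fs") <- fs
  class(out) <- c("gaze_trace", class(out))
  out
}

# pick a landing point at exactly `mag` degrees from `pos`, preferring
# directions that keep gaze inside the centered square [-b, b]^2; the
# magnitude is never compromised (bounds are soft)
saccade_target <- function(pos, mag, b) {
  for (i in seq_len(50)) {
    theta <- runif(1, 0, 2 * pi)
    cand <- pos + mag * c(cos(theta), sin(theta))
    if (all(abs(cand) <= b)) return(cand)
  }
  d <- -pos / max(sqrt(sum(pos^2)), 1e-9)
  pos + mag * d
}
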