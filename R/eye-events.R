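#' Screen geometry
#'
#' @param viewing_distance_cm eye-to-screen distance, cm.
#' @param pixel_density_dpi screen pixel density, pixels per inch.
#' @param stimulus_width_deg stimulus width, visual degrees.
#' @param stimulus_height_deg stimulus height; defaults to 3/4 of the
#'   width (the paradigm states only the width).
#' @return a `screen_geometry` list.
#' @export
screen_geometry <- function(viewing_distance_cm = 70,
                            pixel_density_dpi = 78.5,
                            stimulus_width_deg = 15.8,
                            stimulus_height_deg = stimulus_width_deg * 3 / 4) {
  stopifnot(viewing_distance_cm > 0, pixel_density_dpi > 0,
            stimulus_width_deg > 0, stimulus_height_deg > 0)
  structure(list(viewing_distance_cm = viewing_distance_cm,
                 pixel_density_dpi = pixel_density_dpi,
                 stimulus_width_deg = stimulus_width_deg,
                 stimulus_height_deg = stimulus_height_deg),
            class = "screen_geometry")
}

#' Convert an on-screen displacement from pixels to visual degrees
#'
#' Uses the full arctangent formula
#' `2 * atan((px / dpi * 2.54) / (2 * distance))`, which reproduces the
#' study's conversions (50 px -> 1.3 degrees, 140 px -> 3.7 degrees at
#' 78.5 DPI and 70 cm) and remains correct for large displacements where
#' the small-angle approximation drifts.
#'
#' @param px displacement in pixels (non-negative, vectorized).
#' @param geometry a [screen_geometry()].
#' @return displacement in visual degrees.
#' @examples
#' round(pixels_to_degrees(c(50, 140), screen_geometry()), 1) # 1.3, 3.7
#' @export
pixels_to_degrees <- function(px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"), all(px >= 0))
  size_cm <- px / geometry$pixel_density_dpi * 2.54
  2 * atan(size_cm / (2 * geometry$viewing_distance_cm)) * 180 / pi
}

#' Detect saccades in a gaze trace by speed thresholding
#'
#' Maximal runs of gaze speed above `velocity_threshold` lasting at least
#' `min_duration_ms` become saccade events. The magnitude is the
#' Euclidean distance between the mean fixation positions in short
#' windows flanking the run (amplitude, not path length). Runs that
#' include or touch invalid samples are flagged `encompasses_blink`.
#'
#' @param gaze a gaze tibble (`time_ms`, `x_deg`, `y_deg`, `valid`) on a
#'   uniform grid, e.g. from [simulate_gaze()].
#' @param velocity_threshold speed threshold, degrees per second.
#' @param min_duration_ms minimum run duration, ms.
#' @param fixation_window_ms width of the flanking windows used to
#'   estimate the pre/post fixation positions, ms.
#' @return tibble of saccade events: `onset_ms`, `offset_ms`,
#'   `magnitude_deg`, `encompasses_blink`, `stratum` (from
#'   [select_matched_saccades()]'s rule, see that function for the
#'   boundaries).
#' @export
detect_saccades <- function(gaze, velocity_threshold = 30,
                            min_duration_ms = 6,
                            fixation_window_ms = 20) {
  dt_ms <- diff(gaze$time_ms[1:2])
  if (any(abs(diff(gaze$time_ms) - dt_ms) > 1e-6))
    stop("gaze trace must be uniformly sampled", call. = FALSE)
  n <- nrow(gaze)
  empty <- tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                          magnitude_deg = numeric(0),
                          encompasses_blink = logical(0),
                          stratum = character(0))
  if (!any(gaze$valid)) return(empty)
  vx <- c(0, diff(gaze$x_deg)) / (dt_ms / 1000)
  vy <- c(0, diff(gaze$y_deg)) / (dt_ms / 1000)
  speed <- sqrt(vx^2 + vy^2)
  speed[!gaze$valid] <- 0
  fast <- speed > velocity_threshold
  runs <- rle_runs(fast)
  runs <- runs[runs$value & (runs$end - runs$start + 1) * dt_ms >=
                 min_duration_ms, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  w <- max(1L, round(fixation_window_ms / dt_ms))
  out <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; b <- runs$end[i]
    pre <- max(1L, a - w):(a - 1L)
    post <- (b + 1L):min(n, b + w)
    pre <- pre[pre >= 1]; post <- post[post <= n]
    p0 <- c(mean(gaze$x_deg[pre]), mean(gaze$y_deg[pre]))
    p1 <- c(mean(gaze$x_deg[post]), mean(gaze$y_deg[post]))
    blink <- any(!gaze$valid[max(1L, a - 1L):min(n, b + 1L)])
    tibble::tibble(onset_ms = gaze$time_ms[a], offset_ms = gaze$time_ms[b],
                   magnitude_deg = sqrt(sum((p1 - p0)^2)),
                   encompasses_blink = blink)
  })
  out <- dplyr::bind_rows(out)
  out$stratum <- magnitude_stratum(out$magnitude_deg)
  out
}

rle_runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = end - r$lengths + 1L, end = end)
}

magnitude_stratum <- function(mag, range_deg = c(1.3, 3.7)) {
  ifelse(mag < range_deg[1], "below_range",
         ifelse(mag > range_deg[2], "above_range", "in_range"))
}

#' Select saccades magnitude-matched to the external displacements
#'
#' Saccades encompassing blinks are removed entirely. The remainder is
#' partitioned into `below_range`, `in_range` and `above_range` strata
#' relative to the (inclusive) displacement magnitude range; only
#' `in_range` saccades enter the displacement contrast, while all strata
#' enter the GLM as separate predictor sets.
#'
#' @param saccades tibble from [detect_saccades()] (needs
#'   `magnitude_deg` and `encompasses_blink`).
#' @param range_deg inclusive magnitude range matched to the external
#'   displacements, degrees.
#' @return the non-excluded saccades with a recomputed `stratum` column.
#' @export
select_matched_saccades <- function(saccades, range_deg = c(1.3, 3.7)) {
  stopifnot(range_deg[1] < range_deg[2])
  keep <- saccades[!saccades$encompasses_blink, , drop = FALSE]
  keep$stratum <- magnitude_stratum(keep$magnitude_deg, range_deg)
  keep
}

#' Build the gaze-validity rejection mask
#'
#' Episodes where tracking failed or gaze left the stimulus borders are
#' flagged, padded by 50 ms before and 250 ms after, and merged. Episodes
#' fully explained by blinks are exempt (blink responses are modeled as
#' regressors instead of discarded).
#'
#' @param gaze gaze tibble (`time_ms`, `x_deg`, `y_deg`, `valid`).
#' @param geometry a [screen_geometry()]; the stimulus border is the
#'   centered `stimulus_width_deg` x `stimulus_height_deg` rectangle.
#' @param blink_intervals data frame of blink `onset_ms`/`offset_ms`
#'   intervals (or `NULL`).
#' @param pad_before_ms,pad_after_ms padding applied to each episode.
#' @return a `rejection_mask`: tibble of merged `start_ms`/`end_ms`
#'   intervals.
#' @export
build_rejection_mask <- function(gaze, geometry = screen_geometry(),
                                 blink_intervals = NULL,
                                 pad_before_ms = 50, pad_after_ms = 250) {
  half_w <- geometry$stimulus_width_deg / 2
  half_h <- geometry$stimulus_height_deg / 2
  bad <- !gaze$valid | abs(gaze$x_deg) > half_w | abs(gaze$y_deg) > half_h
  runs <- rle_runs(bad)
  runs <- runs[runs$value, , drop = FALSE]
  dt_ms <- diff(gaze$time_ms[1:2])
  iv <- list()
  for (i in seq_len(nrow(runs))) {
    a <- gaze$time_ms[runs$start[i]]
    b <- gaze$time_ms[runs$end[i]] + dt_ms
    if (!is.null(blink_intervals) && nrow(blink_intervals) > 0) {
      covered <- any(blink_intervals$onset_ms <= a + dt_ms / 2 &
                       blink_intervals$offset_ms >= b - dt_ms / 2)
      if (covered) next
    }
    iv[[length(iv) + 1L]] <- c(max(0, a - pad_before_ms), b + pad_after_ms)
  }
  rejection_mask(do.call(rbind, iv))
}

#' Rejection-mask constructor
#'
#' @param intervals two-column matrix or data frame of start/end times in
#'   ms (may be `NULL` for an empty mask); overlapping intervals are
#'   merged.
#' @return a `rejection_mask` tibble with `start_ms`, `end_ms`.
#' @export
rejection_mask <- function(intervals = NULL) {
  if (is.null(intervals) || NROW(intervals) == 0) {
    out <- tibble::tibble(start_ms = numeric(0), end_ms = numeric(0))
  } else {
    intervals <- as.matrix(intervals)
    out <- merge_intervals(intervals[, 1], intervals[, 2])
  }
  class(out) <- c("rejection_mask", class(out))
  out
}

merge_intervals <- function(start, end) {
  stopifnot(all(end > start))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start_ms = unname(c(outs, ms)),
                 end_ms = unname(c(oute, me)))
}

#' Samples covered by a rejection mask
#'
#' @param mask a [rejection_mask()].
#' @param n number of samples in the recording.
#' @param fs sampling rate, Hz.
#' @return logical vector, `TRUE` where the sample is masked out.
#' @export
mask_samples <- function(mask, n, fs) {
  bad <- rep(FALSE, n)
  for (i in seq_len(nrow(mask))) {
    j0 <- max(1L, floor(mask$start_ms[i] / 1000 * fs) + 1L)
    j1 <- min(n, ceiling(mask$end_ms[i] / 1000 * fs))
    if (j1 >= j0) bad[j0:j1] <- TRUE
  }
  bad
}
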