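#' Simulate one subject's event schedule
#'
#' Lay out blocks of ten 1-s image trials separated by gray baselines and
#' populate them with events: one stimulus onset per trial (face or
#' non-face), exactly one horizontal displacement per fixation-block trial
#' at a latency of 300, 500 or 700 ms and a magnitude of 1.3 or 3.7
#' degrees, Poisson free-viewing saccades with log-normal magnitudes,
#' Poisson blinks, and brief blank-frame gaps during free-viewing trials.
#' Saccade events are labeled by magnitude stratum relative to the
#' displacement range (`saccade_below`, `saccade_in_range`,
#' `saccade_above`), mirroring what detection plus magnitude matching
#' produce on real gaze data.
#'
#' @param config a [sim_config()].
#' @param subject subject identifier.
#' @param seed optional seed for this schedule; defaults to a sub-stream
#'   of `config$seed` keyed by `subject`.
#' @return a tibble with columns `event_id`, `subject`, `block`, `trial`,
#'   `condition`, `onset_ms`, `offset_ms`, `magnitude_deg`,
#'   `magnitude_px`, `face`, `excluded`, plus attributes `blocks` (block
#'   layout tibble with `block`, `start_ms`, `end_ms`, `type`) and
#'   `duration_ms`.
#' @export
simulate_event_schedule <- function(config, subject = 1L, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- substream_seeds(config$seed, 1000L)[subject]
  set.seed(seed)

  block_len <- config$trials_per_block * config$trial_ms
  duration <- config$interblock_ms +
    config$n_blocks * (block_len + config$interblock_ms)
  n_fix <- round(config$fixation_fraction * config$n_blocks)
  block_type <- sample(rep(c("fixation", "free"),
                           c(n_fix, config$n_blocks - n_fix)))
  block_start <- config$interblock_ms +
    (seq_len(config$n_blocks) - 1) * (block_len + config$interblock_ms)
  blocks <- tibble::tibble(block = seq_len(config$n_blocks),
                           start_ms = block_start,
                           end_ms = block_start + block_len,
                           type = block_type)

  ev <- list()
  # stimulus onsets, one per trial
  for (b in seq_len(config$n_blocks)) {
    t0 <- blocks$start_ms[b] + (seq_len(config$trials_per_block) - 1) *
      config$trial_ms
    face <- runif(config$trials_per_block) < config$face_fraction
    target <- runif(config$trials_per_block) < config$target_fraction
    ev[[length(ev) + 1L]] <- tibble::tibble(
      block = b, trial = seq_len(config$trials_per_block),
      condition = ifelse(face, "stimulus_face", "stimulus_nonface"),
      onset_ms = t0, offset_ms = t0 + config$trial_ms,
      magnitude_deg = NA_real_, magnitude_px = NA_real_,
      face = face, excluded = target)
    if (blocks$type[b] == "fixation") {
      lat <- sample(config$displacement_latencies_ms,
                    config$trials_per_block, replace = TRUE)
      which_mag <- sample(seq_along(config$displacement_magnitudes_deg),
                          config$trials_per_block, replace = TRUE)
      mag <- config$displacement_magnitudes_deg[which_mag]
      ev[[length(ev) + 1L]] <- tibble::tibble(
        block = b, trial = seq_len(config$trials_per_block),
        condition = ifelse(mag <= min(config$displacement_magnitudes_deg),
                           "displacement_small", "displacement_large"),
        onset_ms = t0 + lat, offset_ms = t0 + lat,
        magnitude_deg = mag,
        magnitude_px = config$displacement_magnitudes_px[which_mag],
        face = face, excluded = target)
    } else {
      # free viewing: saccades and blank-frame gaps
      sacc <- poisson_events(blocks$start_ms[b], blocks$end_ms[b],
                             config$saccade_rate_hz)
      if (length(sacc)) {
        mag <- truncated_lnorm(length(sacc), config$saccade_meanlog,
                               config$saccade_sdlog, config$saccade_range_deg)
        dur <- 21 + 2.2 * mag   # main-sequence-like duration
        keep <- !overlaps_previous(sacc, sacc + dur, min_gap = 20)
        sacc <- sacc[keep]; mag <- mag[keep]; dur <- dur[keep]
        if (length(sacc)) {
          lo <- min(config$displacement_magnitudes_deg)
          hi <- max(config$displacement_magnitudes_deg)
          stratum <- ifelse(mag < lo, "saccade_below",
                            ifelse(mag > hi, "saccade_above",
                                   "saccade_in_range"))
          tr <- pmin(pmax(floor((sacc - blocks$start_ms[b]) /
                                  config$trial_ms) + 1, 1),
                     config$trials_per_block)
          ev[[length(ev) + 1L]] <- tibble::tibble(
            block = b, trial = as.integer(tr), condition = stratum,
            onset_ms = sacc, offset_ms = sacc + dur,
            magnitude_deg = mag, magnitude_px = NA_real_,
            face = face[tr], excluded = target[tr])
        }
      }
      gaps <- poisson_events(blocks$start_ms[b],
                             blocks$end_ms[b] - config$gap_ms,
                             config$gap_rate_hz)
      if (length(gaps)) {
        tr <- pmin(pmax(floor((gaps - blocks$start_ms[b]) /
                                config$trial_ms) + 1, 1),
                   config$trials_per_block)
        ev[[length(ev) + 1L]] <- tibble::tibble(
          block = b, trial = as.integer(tr), condition = "gap",
          onset_ms = gaps, offset_ms = gaps + config$gap_ms,
          magnitude_deg = NA_real_, magnitude_px = NA_real_,
          face = face[tr], excluded = target[tr])
      }
    }
  }
  # blinks anywhere in the recording
  bl <- poisson_events(0, duration - max(config$blink_duration_ms),
                       config$blink_rate_hz)
  if (length(bl)) {
    dur <- runif(length(bl), config$blink_duration_ms[1],
                 config$blink_duration_ms[2])
    keep <- !overlaps_previous(bl, bl + dur, min_gap = 50)
    bl <- bl[keep]; dur <- dur[keep]
    ev[[length(ev) + 1L]] <- tibble::tibble(
      block = NA_integer_, trial = NA_integer_, condition = "blink",
      onset_ms = bl, offset_ms = bl + dur,
      magnitude_deg = NA_real_, magnitude_px = NA_real_,
      face = NA, excluded = FALSE)
  }

  out <- dplyr::bind_rows(ev) %>%
    dplyr::arrange(.data$onset_ms) %>%
    dplyr::mutate(event_id = dplyr::row_number(),
                  subject = subject, .before = 1)
  # drop saccades that overlap a blink: they would be excluded downstream
  blink_iv <- out[out$condition == "blink", c("onset_ms", "offset_ms")]
  is_sacc <- startsWith(out$condition, "saccade")
  if (nrow(blink_iv) && any(is_sacc)) {
    hit <- intervals_overlap(out$onset_ms[is_sacc], out$offset_ms[is_sacc],
                             blink_iv$onset_ms, blink_iv$offset_ms)
    out <- out[!(is_sacc & replace_in(is_sacc, hit)), ]
    out$event_id <- seq_len(nrow(out))
  }
  attr(out, "blocks") <- blocks
  attr(out, "duration_ms") <- duration
  attr(out, "fs") <- config$fs
  out
}

# homogeneous Poisson event onsets on [from, to)
poisson_events <- function(from, to, rate_hz) {
  if (rate_hz <= 0 || to <= from) return(numeric(0))
  span_s <- (to - from) / 1000
  n <- stats::rpois(1, rate_hz * span_s)
  sort(runif(n, from, to))
}

truncated_lnorm <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

# TRUE where event i starts before event i-1 (plus min_gap) has ended
overlaps_previous <- function(onset, offset, min_gap = 0) {
  n <- length(onset)
  if (n <= 1) return(rep(FALSE, n))
  bad <- logical(n)
  last_off <- offset[1]
  for (i in 2:n) {
    if (onset[i] < last_off + min_gap) bad[i] <- TRUE
    else last_off <- offset[i]
  }
  bad
}

# for each [a1,b1] interval, does it overlap any [a2,b2]?
intervals_overlap <- function(a1, b1, a2, b2) {
  vapply(seq_along(a1), function(i) any(a1[i] < b2 & b1[i] > a2), logical(1))
}

# scatter values of `x` (defined on which(mask)) back onto mask positions
replace_in <- function(mask, x) {
  out <- logical(length(mask))
  out[mask] <- x
  out
}
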