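#' Simulation configuration
#'
#' Bundle every parameter of the synthetic cohort: the event schedule
#' (blocks of ten 1-s image trials separated by 3-s gray baselines;
#' fixation blocks carrying one horizontal displacement of 1.3 or 3.7
#' visual degrees per trial at 300, 500 or 700 ms; free-viewing blocks
#' carrying spontaneous saccades and blank-frame gaps), the per-condition
#' response kernels, the per-ROI saccade/blink suppression factors, and
#' the AR(1) noise model.
#'
#' A suppression factor `s` in `[0, 1]` scales the saccade kernel to
#' `(1 - s)` times the displacement kernel (and likewise the blink kernel
#' relative to the gap kernel), so `s = 0` means identical responses and
#' `s = 1` means complete suppression of the self-generated transient.
#' The implied true suppression index is `s / (2 - s)`.
#'
#' @param n_subjects number of simulated subjects.
#' @param electrodes_per_roi named integer vector, electrodes per ROI over
#'   the whole cohort (assigned to subjects round-robin).
#' @param kernels named list of [kernel_spec()] objects for conditions
#'   `stimulus_face`, `stimulus_nonface`, `displacement`, `saccade`,
#'   `gap`, `blink`. The displacement spec is shared by both magnitudes;
#'   the saccade spec before suppression equals the displacement spec by
#'   default.
#' @param suppression_factor named numeric vector in `[0, 1]` per ROI.
#' @param ar1 lag-one autocorrelation of the additive noise.
#' @param innovation_sd innovation SD of the AR(1) noise; the default
#'   `sqrt(1 - ar1^2)` gives the noise unit marginal variance, i.e.
#'   baseline-SD units.
#' @param n_blocks,trials_per_block,trial_ms,interblock_ms schedule
#'   geometry (defaults: 44 blocks of ten 1000-ms trials, 3000-ms gray
#'   baselines).
#' @param fixation_fraction fraction of blocks that are fixation blocks
#'   carrying external displacements (default 12/44).
#' @param displacement_latencies_ms allowed displacement latencies from
#'   trial onset, ms.
#' @param displacement_magnitudes_deg,displacement_magnitudes_px the two
#'   displacement sizes (50 and 140 px at the default screen geometry).
#' @param saccade_rate_hz free-viewing saccade rate, events per second.
#' @param saccade_meanlog,saccade_sdlog,saccade_range_deg log-normal
#'   saccade magnitude distribution, truncated to `saccade_range_deg` so
#'   all three magnitude strata (below / in / above 1.3--3.7 degrees) are
#'   populated.
#' @param blink_rate_hz spontaneous blink rate, events per second.
#' @param blink_duration_ms range of blink durations, ms.
#' @param gap_rate_hz rate of blank-frame gaps during free-viewing
#'   trials, events per second.
#' @param gap_ms blank-frame duration, ms.
#' @param peak_jitter_sd_ms SD of a per-electrode latency offset added to
#'   the displacement and saccade kernel peaks (a shared "retinal lag"
#'   per electrode), ms; gives electrodes heterogeneous but
#'   condition-correlated response latencies.
#' @param face_fraction fraction of face trials.
#' @param target_fraction fraction of animal-target trials, which are
#'   flagged `excluded` and dropped from modeling.
#' @param fs analysis sampling rate of the simulated HFB traces, Hz.
#' @param gaze_fs gaze sampling rate, Hz.
#' @param seed master seed; all sub-streams are derived from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 12,
                       electrodes_per_roi = c(V1 = 15, V2 = 11, V3 = 12,
                                              V4 = 6, VO = 6, Face = 15,
                                              HighLevel = 18),
                       kernels = default_kernels(),
                       suppression_factor = c(V1 = 0, V2 = 0, V3 = 0,
                                              V4 = 1, VO = 1, Face = 1,
                                              HighLevel = 1),
                       ar1 = 0.8,
                       innovation_sd = sqrt(1 - ar1^2),
                       n_blocks = 44,
                       trials_per_block = 10,
                       trial_ms = 1000,
                       interblock_ms = 3000,
                       fixation_fraction = 12 / 44,
                       displacement_latencies_ms = c(300, 500, 700),
                       displacement_magnitudes_deg = c(1.3, 3.7),
                       displacement_magnitudes_px = c(50, 140),
                       saccade_rate_hz = 2,
                       saccade_meanlog = log(2),
                       saccade_sdlog = 0.6,
                       saccade_range_deg = c(0.2, 8),
                       blink_rate_hz = 0.15,
                       blink_duration_ms = c(150, 300),
                       gap_rate_hz = 0.1,
                       gap_ms = 200,
                       peak_jitter_sd_ms = 20,
                       face_fraction = 0.5,
                       target_fraction = 0,
                       fs = 100,
                       gaze_fs = 500,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    electrodes_per_roi = electrodes_per_roi,
    kernels = kernels,
    suppression_factor = suppression_factor,
    ar1 = ar1, innovation_sd = innovation_sd,
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    trial_ms = trial_ms, interblock_ms = interblock_ms,
    fixation_fraction = fixation_fraction,
    displacement_latencies_ms = displacement_latencies_ms,
    displacement_magnitudes_deg = displacement_magnitudes_deg,
    displacement_magnitudes_px = displacement_magnitudes_px,
    saccade_rate_hz = saccade_rate_hz,
    saccade_meanlog = saccade_meanlog,
    saccade_sdlog = saccade_sdlog,
    saccade_range_deg = saccade_range_deg,
    blink_rate_hz = blink_rate_hz,
    blink_duration_ms = blink_duration_ms,
    gap_rate_hz = gap_rate_hz, gap_ms = gap_ms,
    peak_jitter_sd_ms = peak_jitter_sd_ms,
    face_fraction = face_fraction,
    target_fraction = target_fraction,
    fs = fs, gaze_fs = gaze_fs,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_kernels <- function() {
  list(
    stimulus_face    = kernel_spec(amplitude = 5, peak_ms = 200, width_ms = 80),
    stimulus_nonface = kernel_spec(amplitude = 4, peak_ms = 200, width_ms = 80),
    displacement     = kernel_spec(amplitude = 3, peak_ms = 170, width_ms = 60),
    saccade          = kernel_spec(amplitude = 3, peak_ms = 170, width_ms = 60),
    gap              = kernel_spec(amplitude = 2.5, peak_ms = 180, width_ms = 60),
    blink            = kernel_spec(amplitude = 2.5, peak_ms = 180, width_ms = 60)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1,
            all(cfg$electrodes_per_roi >= 0),
            !is.null(names(cfg$electrodes_per_roi)))
  if (!all(names(cfg$electrodes_per_roi) %in% names(cfg$suppression_factor)))
    stop("every ROI needs a suppression factor", call. = FALSE)
  if (any(cfg$suppression_factor < 0 | cfg$suppression_factor > 1))
    stop("suppression_factor must lie in [0, 1]", call. = FALSE)
  if (!setequal(cfg$displacement_latencies_ms, c(300, 500, 700)))
    stop("displacement latencies must be drawn from {300, 500, 700} ms",
         call. = FALSE)
  if (cfg$trials_per_block != 10L)
    stop("trials_per_block is fixed at 10 by the paradigm", call. = FALSE)
  pos <- c(cfg$trial_ms, cfg$interblock_ms, cfg$fs, cfg$gaze_fs, cfg$gap_ms,
           cfg$blink_duration_ms)
  if (any(pos <= 0)) stop("all durations and rates must be positive",
                          call. = FALSE)
  if (cfg$peak_jitter_sd_ms < 0)
    stop("peak_jitter_sd_ms must be non-negative", call. = FALSE)
  if (cfg$saccade_rate_hz < 0 || cfg$blink_rate_hz < 0 || cfg$gap_rate_hz < 0)
    stop("event rates must be non-negative", call. = FALSE)
  if (cfg$fixation_fraction < 0 || cfg$fixation_fraction > 1)
    stop("fixation_fraction must lie in [0, 1]", call. = FALSE)
  if (abs(cfg$ar1) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1",
                              call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects, %d electrodes in %d ROIs\n", x$n_subjects,
              sum(x$electrodes_per_roi), length(x$electrodes_per_roi)))
  cat(sprintf("  %d blocks x %d trials (%.0f ms) + %.0f ms baselines; %.0f%% fixation blocks\n",
              x$n_blocks, x$trials_per_block, x$trial_ms, x$interblock_ms,
              100 * x$fixation_fraction))
  cat(sprintf("  AR(1) phi = %.2f, innovation SD = %.3f, fs = %g Hz\n",
              x$ar1, x$innovation_sd, x$fs))
  invisible(x)
}

# deterministic sub-stream seeds derived from the master seed
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' True suppression index implied by a suppression factor
#'
#' With the saccade response scaled by `(1 - s)` relative to the
#' displacement response, the index `(d - s)/(d + s)` equals
#' `s / (2 - s)`.
#'
#' @param s suppression factor in `[0, 1]`.
#' @return the implied suppression index.
#' @export
implied_suppression_index <- function(s) s / (2 - s)

#' Suppression factor that realizes a target true index
#'
#' Inverse of [implied_suppression_index()]: `s = 2 i / (1 + i)`.
#'
#' @param i target suppression index in `[0, 1]`.
#' @return the suppression factor.
#' @export
suppression_factor_for_index <- function(i) 2 * i / (1 + i)
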