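#' Canned validation experiments
#'
#' These functions package the study-style simulation experiments that
#' the analysis scripts, the test suite and the acceptance script all
#' run: each builds its own synthetic data with known ground truth,
#' executes the corresponding pipeline stage, and returns the measured
#' quantities. Sizes default to desk-scale versions of the study
#' conditions (documented in the methods vignette).
#'
#' @name experiments
NULL

# lean two-condition design used by the label-shuffle experiments:
# pooled displacements vs magnitude-matched saccades, intercept nuisance
lean_contrast_spec <- function() {
  ev <- list(window = c(-300, 500), align = "offset")
  design_spec(conditions = list(displacement = ev, saccade_in_range = ev))
}

lean_schedule <- function(config, seed) {
  sch <- simulate_event_schedule(config, subject = 1L, seed = seed)
  keep <- startsWith(sch$condition, "displacement") |
    sch$condition == "saccade_in_range"
  out <- sch[keep, ]
  attr(out, "duration_ms") <- attr(sch, "duration_ms")
  attr(out, "blocks") <- attr(sch, "blocks")
  out
}

#' @describeIn experiments Exact recovery of overlapping kernels by the
#'   FIR GLM on a noiseless recording, against the bias of naive
#'   event-locked averaging. Returns the maximum absolute recovery error
#'   over all conditions and lags, and the maximum absolute bias of the
#'   naive displacement average.
#' @param seed seed for the schedule (the recording is noiseless).
#' @export
experiment_deconv_oracle <- function(seed = 1L) {
  config <- sim_config(n_subjects = 1, electrodes_per_roi = c(V1 = 1),
                       n_blocks = 10, fixation_fraction = 0.5,
                       peak_jitter_sd_ms = 0, seed = seed)
  sch <- simulate_event_schedule(config, subject = 1L)
  kern <- lapply(config$kernels, realize_kernel, fs = config$fs)
  rec <- simulate_hfb(sch, kern, fs = config$fs, noise = FALSE)
  spec <- design_spec()
  D <- build_design_matrix(sch, spec, n_samples = nrow(rec$data),
                           fs = config$fs)
  fit <- fit_fir_glm(rec$data[, 1], D)
  err <- vapply(unique(fit$trace$condition), function(cn) {
    tr <- get_trace(fit, cn)
    k <- resolve_kernel(kern, cn)
    full <- numeric(nrow(tr))
    pos <- match(round(attr(k, "time_ms")), round(tr$time_ms))
    full[pos[!is.na(pos)]] <- k[!is.na(pos)]
    max(abs(tr$coef - full))
  }, numeric(1))
  naive <- event_locked_average(rec$data[, 1], sch, "displacement",
                                window = c(0, 500), fs = config$fs)
  naive_bias <- max(abs(naive$mean - kern$displacement))
  list(max_recovery_error = max(err), per_condition = err,
       naive_bias = naive_bias,
       n_samples = nrow(rec$data))
}

#' @describeIn experiments Type-I error calibration of the cluster-area
#'   label-shuffle test: electrodes whose displacement and saccade
#'   kernels are identical (no suppression), independent schedules and
#'   AR(1) noise per electrode. Returns the per-electrode one-sided
#'   p-values and the empirical rejection rate at `alpha`.
#' @param n_electrodes number of simulated null electrodes.
#' @param n_perm label shuffles per electrode.
#' @param alpha nominal level.
#' @export
experiment_type1_calibration <- function(n_electrodes = 200, n_perm = 500,
                                         alpha = 0.05, seed = 1L) {
  config <- sim_config(n_subjects = 1, electrodes_per_roi = c(V1 = 1),
                       n_blocks = 10, fixation_fraction = 0.5,
                       peak_jitter_sd_ms = 0, seed = seed)
  kern <- lapply(config$kernels, realize_kernel, fs = config$fs)
  kern$saccade <- kern$displacement       # identical kernels: exact null
  spec <- lean_contrast_spec()
  ss <- substream_seeds(seed, 3L * n_electrodes)
  p <- vapply(seq_len(n_electrodes), function(i) {
    sch <- lean_schedule(config, seed = ss[i])
    rec <- simulate_hfb(sch, kern, ar1 = config$ar1,
                        innovation_sd = config$innovation_sd,
                        fs = config$fs, seed = ss[n_electrodes + i])
    pt <- cluster_area_perm_test(rec$data[, 1], sch, spec,
                                 fs = config$fs, n_perm = n_perm,
                                 seed = ss[2L * n_electrodes + i])
    pt$p_pos_gt_neg
  }, numeric(1))
  list(p_values = p, rejection_rate = mean(p <= alpha),
       n_electrodes = n_electrodes, n_perm = n_perm, alpha = alpha)
}

#' @describeIn experiments Power of the cluster-area test under complete
#'   saccadic suppression: displacement kernel of `amplitude` baseline
#'   SDs, saccade kernel zero, `n_events` events per condition. Returns
#'   the fraction of simulations detecting the difference at
#'   `p < p_threshold`.
#' @param n_sims number of simulated electrodes.
#' @param n_events events per condition.
#' @param amplitude displacement kernel amplitude, baseline-SD units.
#' @param p_threshold detection threshold on the one-sided p-value.
#' @export
experiment_power <- function(n_sims = 100, n_perm = 500, n_events = 40,
                             amplitude = 5, p_threshold = 0.01,
                             seed = 1L) {
  config <- sim_config(n_subjects = 1, electrodes_per_roi = c(V1 = 1),
                       n_blocks = 16, fixation_fraction = 0.5,
                       peak_jitter_sd_ms = 0, seed = seed)
  base <- config$kernels$displacement
  kern <- list(
    displacement = realize_kernel(
      kernel_spec(amplitude, base$peak_ms, base$width_ms),
      fs = config$fs),
    saccade = numeric(50))
  spec <- lean_contrast_spec()
  ss <- substream_seeds(seed + 1L, 3L * n_sims)
  p <- vapply(seq_len(n_sims), function(i) {
    sch <- lean_schedule(config, seed = ss[i])
    # exactly n_events per condition
    set.seed(ss[i])
    disp <- which(startsWith(sch$condition, "displacement"))
    sacc <- which(sch$condition == "saccade_in_range")
    if (length(disp) < n_events || length(sacc) < n_events)
      stop("schedule too short for requested event count", call. = FALSE)
    keep <- sort(c(sample(disp, n_events), sample(sacc, n_events)))
    sch2 <- sch[keep, ]
    attr(sch2, "duration_ms") <- attr(sch, "duration_ms")
    rec <- simulate_hfb(sch2, kern, ar1 = config$ar1,
                        innovation_sd = config$innovation_sd,
                        fs = config$fs, seed = ss[n_sims + i])
    cluster_area_perm_test(rec$data[, 1], sch2, spec, fs = config$fs,
                           n_perm = n_perm,
                           seed = ss[2L * n_sims + i])$p_pos_gt_neg
  }, numeric(1))
  list(p_values = p, detection_rate = mean(p < p_threshold),
       n_sims = n_sims, n_events = n_events, n_perm = n_perm)
}

#' @describeIn experiments Recovery of known suppression indices from
#'   cross-validated response scalars: three ROIs with true indices
#'   `true_indices`, study-like SNR. Returns per-ROI recovered means and
#'   absolute errors.
#' @param true_indices true saccadic suppression indices per ROI.
#' @param electrodes_per_roi electrodes per ROI.
#' @param n_subjects,n_blocks cohort size.
#' @param n_folds cross-validation folds.
#' @export
experiment_index_recovery <- function(true_indices = c(0, 0.5, 1),
                                      electrodes_per_roi = 6,
                                      n_subjects = 3, n_blocks = 20,
                                      n_folds = 5, seed = 1L) {
  rois <- sprintf("ROI_%g", true_indices)
  epr <- setNames(rep(electrodes_per_roi, length(rois)), rois)
  supp <- setNames(suppression_factor_for_index(true_indices), rois)
  config <- sim_config(n_subjects = n_subjects, electrodes_per_roi = epr,
                       suppression_factor = supp, n_blocks = n_blocks,
                       fixation_fraction = 0.5, seed = seed)
  cohort <- simulate_cohort(config)
  spec <- design_spec(pool_displacements = TRUE)
  scal <- list()
  for (s in seq_len(n_subjects)) {
    rec <- cohort$recordings[[s]]
    if (is.null(rec)) next
    sch <- cohort$schedules[[s]]
    D <- build_design_matrix(sch, spec, n_samples = nrow(rec$data),
                             fs = config$fs)
    for (e in seq_len(ncol(rec$data))) {
      cv <- crossvalidated_estimates(rec$data[, e], D,
                                     attr(sch, "blocks"),
                                     n_folds = n_folds)
      scal[[length(scal) + 1L]] <- tibble::tibble(
        electrode = rec$electrodes$electrode[e],
        roi = rec$electrodes$roi[e],
        gap = scalar_cond(cv$trace, "gap", c(0, 500)),
        blink = scalar_cond(cv$trace, "blink", c(0, 500)),
        displacement = scalar_cond(cv$trace, "displacement", c(0, 500)),
        saccade = scalar_cond(cv$trace, "saccade_in_range", c(0, 500)))
    }
  }
  si <- suppression_indices(dplyr::bind_rows(scal))
  out <- si$roi
  out$true_index <- true_indices[match(out$roi, rois)]
  out$abs_error <- abs(out$saccade_mean - out$true_index)
  list(roi = out, electrodes = si$electrodes,
       max_abs_error = max(out$abs_error))
}

#' @describeIn experiments End-to-end hierarchy gradient: a cohort with
#'   no suppression in early-ROI analogs (V1-V3) and complete
#'   suppression in higher-level analogs (V4, VO, face-selective,
#'   high-level), run through the full pipeline. Returns the fractions
#'   of significant displacement-greater electrodes in the early and
#'   high-level groups.
#' @param per_roi electrodes per ROI.
#' @param alpha FDR threshold defining the significance maps.
#' @export
experiment_gradient <- function(n_subjects = 3, per_roi = 3,
                                n_blocks = 16, n_perm = 300,
                                alpha = 0.05, seed = 1L) {
  config <- sim_config(
    n_subjects = n_subjects,
    electrodes_per_roi = setNames(rep(per_roi, 7),
                                  c("V1", "V2", "V3", "V4", "VO", "Face",
                                    "HighLevel")),
    n_blocks = n_blocks, fixation_fraction = 0.5, seed = seed)
  run <- run_pipeline(config, n_perm = n_perm, n_rand = 2000,
                      n_perm_dice = 5000, n_shuffle_corr = 1000,
                      alpha = alpha)
  early <- c("V1", "V2", "V3")
  high <- c("V4", "VO", "Face", "HighLevel")
  frac <- function(rois) {
    sub <- run$electrode_map[run$electrode_map$roi %in% rois, ]
    mean(sub$q_pos_gt_neg < alpha)
  }
  list(run = run, frac_early = frac(early), frac_high = frac(high),
       roi_counts = run$roi_counts)
}
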