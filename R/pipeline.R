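#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates the end-to-end analysis: simulate the cohort, screen
#' electrodes for visual responsiveness, deconvolve every electrode's
#' HFB trace with the FIR GLM, run the displacement-vs-saccade and
#' gap-vs-blink cluster-area permutation contrasts, FDR-correct across
#' electrodes, count significant electrodes per ROI and test the ROI
#' dependence by randomization, measure SE-normalized peak latencies and
#' compare them across conditions, compute cross-validated suppression
#' indices with ROI means, test the overlap of the two significance maps
#' (Dice + permutation), test the ROI-level association of the two
#' indices with the bias-corrected outlier-removal randomization, and
#' assemble ROI grand averages.
#'
#' @param config a [sim_config()]; its seed drives every stochastic
#'   step, so identical configs give identical bundles.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV plus a JSON run log.
#' @param n_perm label shuffles per electrode for the cluster-area
#'   contrasts.
#' @param n_rand shuffles for the ROI independence randomization.
#' @param n_perm_dice permutations for the Dice overlap test.
#' @param n_shuffle_corr shuffles for the outlier-removal correlation
#'   test.
#' @param n_folds cross-validation folds (split by block).
#' @param alpha significance level used for maps and gates.
#' @param scalar_window post-event window for response scalars, ms.
#' @param outlier_roi ROI designated as the outlier in the index
#'   correlation (the analysis is skipped if absent or if fewer than 4
#'   ROIs remain).
#' @param screen include only electrodes passing the visual
#'   responsiveness screen (on by default; synthetic electrodes with a
#'   stimulus kernel virtually always pass).
#' @return a `saccsupp_run` bundle (all tables and test objects).
#' @export
run_pipeline <- function(config, out_dir = NULL, n_perm = 1000,
                         n_rand = 10000, n_perm_dice = 10000,
                         n_shuffle_corr = 2000, n_folds = 5,
                         alpha = 0.05, scalar_window = c(0, 500),
                         outlier_roi = "V4", screen = TRUE) {
  cohort <- simulate_cohort(config)
  meta <- cohort$electrodes
  bundle <- list(config = config, electrodes = meta)
  if (nrow(meta) == 0) {
    message("no electrodes configured: empty run")
    bundle$empty <- TRUE
    if (!is.null(out_dir)) write_bundle(bundle, out_dir)
    return(structure(bundle, class = "saccsupp_run"))
  }
  spec <- design_spec(pool_displacements = TRUE)
  fs <- config$fs
  ss <- substream_seeds(config$seed, 10000L)
  perm_seed <- function(i) ss[5000L + i]

  # per-subject screening, per-electrode fits and permutation contrasts
  fits <- list(); cvs <- list(); perm_ds <- list(); perm_gb <- list()
  screening <- list()
  for (s in seq_len(config$n_subjects)) {
    rec <- cohort$recordings[[s]]
    if (is.null(rec)) next
    events <- cohort$schedules[[s]]
    blocks <- attr(events, "blocks")
    scr <- screen_visual_responsiveness(rec, events)
    screening[[s]] <- scr
    D <- build_design_matrix(events, spec, n_samples = nrow(rec$data),
                             fs = fs)
    for (e in seq_len(ncol(rec$data))) {
      id <- rec$electrodes$electrode[e]
      if (screen && !scr$included[e]) next
      y <- rec$data[, e]
      fits[[id]] <- fit_fir_glm(y, D)
      cvs[[id]] <- crossvalidated_estimates(y, D, blocks,
                                            n_folds = n_folds)
      i <- match(id, meta$electrode)
      perm_ds[[id]] <- cluster_area_perm_test(
        y, events, spec, n_samples = nrow(rec$data), fs = fs,
        cond_pos = "displacement", cond_neg = "saccade_in_range",
        n_perm = n_perm, seed = perm_seed(i))
      perm_gb[[id]] <- cluster_area_perm_test(
        y, events, spec, n_samples = nrow(rec$data), fs = fs,
        cond_pos = "gap", cond_neg = "blink",
        n_perm = n_perm, seed = perm_seed(i + nrow(meta)))
    }
  }
  bundle$screening <- dplyr::bind_rows(screening)
  included_ids <- names(fits)
  meta_inc <- meta[match(included_ids, meta$electrode), ]

  # electrode-level map with FDR across electrodes, per direction
  map_ds <- fdr_across_electrodes(perm_ds, included_ids)
  map_gb <- fdr_across_electrodes(perm_gb, included_ids)
  map_ds <- dplyr::left_join(map_ds, meta[, c("electrode", "roi")],
                             by = "electrode")
  bundle$electrode_map <- map_ds
  bundle$electrode_map_gap_blink <- map_gb

  # ROI counts of significant electrodes and independence randomization
  sig_ds <- map_ds$electrode[map_ds$q_pos_gt_neg < alpha]
  sig_gb <- map_gb$electrode[map_gb$q_pos_gt_neg < alpha]
  roi_counts <- map_ds %>%
    dplyr::group_by(.data$roi) %>%
    dplyr::summarise(n = dplyr::n(),
                     n_significant = sum(.data$q_pos_gt_neg < alpha),
                     .groups = "drop")
  bundle$roi_counts <- roi_counts
  bundle$roi_independence <- tryCatch(
    roi_independence_test(map_ds$roi, map_ds$q_pos_gt_neg < alpha,
                          n_rand = n_rand, seed = ss[9001L]),
    error = function(e) {
      message("ROI independence test skipped: ", conditionMessage(e))
      NULL
    })

  # SE-normalized peak latencies for electrodes responsive to both
  lat <- tibble::tibble(
    electrode = included_ids,
    displacement = vapply(included_ids, function(id)
      peak_latency(fits[[id]], "displacement"), numeric(1)),
    saccade = vapply(included_ids, function(id)
      peak_latency(fits[[id]], "saccade_in_range"), numeric(1)))
  bundle$latencies <- lat
  bundle$latency_comparison <- tryCatch(
    latency_comparison(lat$displacement, lat$saccade),
    error = function(e) {
      message("latency comparison skipped: ", conditionMessage(e))
      NULL
    })

  # cross-validated response scalars and suppression indices
  scal <- dplyr::bind_rows(lapply(included_ids, function(id) {
    cv <- cvs[[id]]$trace
    tibble::tibble(
      electrode = id,
      gap = scalar_cond(cv, "gap", scalar_window),
      blink = scalar_cond(cv, "blink", scalar_window),
      displacement = scalar_cond(cv, "displacement", scalar_window),
      saccade = scalar_cond(cv, "saccade_in_range", scalar_window))
  }))
  scal <- dplyr::left_join(scal, meta[, c("electrode", "roi")],
                           by = "electrode")
  bundle$scalars <- scal
  si <- suppression_indices(scal)
  bundle$suppression <- si

  # overlap of the two significance maps
  bundle$dice <- if (length(sig_ds) + length(sig_gb) > 0) {
    dice_overlap_test(sig_ds, sig_gb, universe = included_ids,
                      n_perm = n_perm_dice, seed = ss[9002L])
  } else NULL

  # ROI-level association of the two indices, V4-style outlier removed
  roi_tab <- si$roi[is.finite(si$roi$blink_mean) &
                      is.finite(si$roi$saccade_mean), ]
  bundle$index_correlation <-
    if (outlier_roi %in% roi_tab$roi && nrow(roi_tab) >= 5) {
      outlier_robust_correlation_test(
        roi_tab$blink_mean, roi_tab$saccade_mean,
        designated_outlier = match(outlier_roi, roi_tab$roi),
        n_shuffle = n_shuffle_corr, seed = ss[9003L])
    } else NULL

  # ROI grand averages of the deconvolved traces
  bundle$deconv <- deconv_table(fits)
  bundle$grand_average <- grand_average(bundle$deconv, meta)

  bundle$seeds <- list(master = config$seed)
  bundle <- structure(bundle, class = "saccsupp_run")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

scalar_cond <- function(cv_trace, condition, window) {
  if (!condition %in% cv_trace$condition) return(NA_real_)
  scalar_response(cv_trace, condition, window)
}

#' @export
print.saccsupp_run <- function(x, ...) {
  cat("<saccsupp_run>\n")
  if (isTRUE(x$empty)) {
    cat("  empty run (no electrodes)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d electrodes analyzed, %d ROIs\n",
              nrow(x$electrode_map), nrow(x$roi_counts)))
  sig <- sum(x$electrode_map$q_pos_gt_neg < 0.05)
  cat(sprintf("  displacement > saccade: %d/%d electrodes significant (q < 0.05)\n",
              sig, nrow(x$electrode_map)))
  if (!is.null(x$dice))
    cat(sprintf("  Dice overlap with gap > blink map: %.3f (p = %.3g)\n",
                x$dice$dice, x$dice$p))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (isTRUE(bundle$empty)) {
    jsonlite::write_json(list(empty = TRUE, seed = bundle$config$seed),
                         p("run_log.json"), auto_unbox = TRUE)
    return(invisible(out_dir))
  }
  write_tsv_file(bundle$electrode_map, p("electrode_map.tsv"))
  write_tsv_file(bundle$electrode_map_gap_blink,
                 p("electrode_map_gap_blink.tsv"))
  write_tsv_file(bundle$roi_counts, p("roi_counts.tsv"))
  write_tsv_file(bundle$latencies, p("latencies.tsv"))
  write_tsv_file(bundle$suppression$electrodes,
                 p("suppression_indices.tsv"))
  write_tsv_file(bundle$suppression$roi, p("suppression_roi.tsv"))
  write_tsv_file(bundle$deconv, p("deconv_traces.tsv"))
  write_tsv_file(bundle$grand_average, p("grand_average.tsv"))
  log <- list(
    seed = bundle$config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("saccsupp")),
    n_electrodes = nrow(bundle$electrode_map),
    roi_independence = if (!is.null(bundle$roi_independence))
      bundle$roi_independence[c("chisq", "df", "p")],
    latency_comparison = bundle$latency_comparison,
    dice = if (!is.null(bundle$dice))
      bundle$dice[c("dice", "p", "n_a", "n_b", "n_universe")],
    index_correlation = if (!is.null(bundle$index_correlation))
      bundle$index_correlation[c("observed_r", "p", "null_center")])
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
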