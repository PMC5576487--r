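#' ROI grand averages with between-subject error
#'
#' Electrode traces are first averaged within subject for each ROI x
#' condition, then averaged across subjects; the SE is the SD of the
#' subject means divided by `sqrt(n_subjects)`. Averaging within subject
#' first means each subject carries equal weight regardless of its
#' electrode count, which is the only reading consistent with an error
#' band described as between-subjects variability. With a single subject
#' the SE is undefined (`NA`).
#'
#' @param traces tidy tibble with columns `electrode`, `condition`,
#'   `time_ms`, `coef` (e.g. stacked `deconv_result$trace`s).
#' @param metadata tibble with `electrode`, `subject`, `roi`.
#' @return tibble with `roi`, `condition`, `time_ms`, `mean`, `se`,
#'   `n_electrodes`, `n_subjects`. ROIs with no electrodes are simply
#'   absent.
#' @export
grand_average <- function(traces, metadata) {
  stopifnot(all(c("electrode", "condition", "time_ms", "coef") %in%
                  names(traces)),
            all(c("electrode", "subject", "roi") %in% names(metadata)))
  x <- dplyr::left_join(traces,
                        metadata[, c("electrode", "subject", "roi")],
                        by = "electrode")
  if (any(is.na(x$roi))) {
    x <- x[!is.na(x$roi), ]
  }
  subj <- x %>%
    dplyr::group_by(.data$roi, .data$condition, .data$time_ms,
                    .data$subject) %>%
    dplyr::summarise(m = mean(.data$coef),
                     n_el = dplyr::n_distinct(.data$electrode),
                     .groups = "drop")
  subj %>%
    dplyr::group_by(.data$roi, .data$condition, .data$time_ms) %>%
    dplyr::summarise(
      mean = mean(.data$m),
      se = if (dplyr::n() > 1) sd(.data$m) / sqrt(dplyr::n()) else NA_real_,
      n_electrodes = sum(.data$n_el),
      n_subjects = dplyr::n(), .groups = "drop")
}

#' Plot ROI grand-average traces (advisory)
#'
#' Trace panels per ROI with an SE ribbon, one color per condition.
#' Requires ggplot2; figures are for inspection only and never feed the
#' statistics.
#'
#' @param ga output of [grand_average()].
#' @return a ggplot object.
#' @export
plot_grand_average <- function(ga) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(ga, ggplot2::aes(x = .data$time_ms, y = .data$mean,
                                   color = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "time from event (ms)",
                  y = "HFB contribution (baseline SD)")
}
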