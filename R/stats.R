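#' Randomization test of independence between ROI and significance
#'
#' The statistic is the Pearson chi-square of the ROI x
#' {significant, not} table; the null is built by shuffling the ROI
#' labels across electrodes while keeping the significance flags fixed,
#' recomputing the statistic each time. The add-one upper-tail p-value
#' is returned.
#'
#' @param roi character/factor vector of ROI labels per electrode.
#' @param significant logical vector per electrode.
#' @param n_rand number of label shuffles.
#' @param seed RNG seed.
#' @return list with `chisq`, `df`, `p`, `table`, `null_stats`.
#' @export
roi_independence_test <- function(roi, significant, n_rand = 10000,
                                  seed = NULL) {
  stopifnot(length(roi) == length(significant))
  roi <- as.character(roi)
  counts <- table(roi)
  if (any(counts == 0)) {
    warning("dropping ROI(s) with zero electrodes")
  }
  roi <- factor(roi)
  if (nlevels(roi) < 2) stop("need at least 2 ROIs", call. = FALSE)
  stat <- function(r) {
    tab <- table(r, factor(significant, levels = c(FALSE, TRUE)))
    suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  }
  observed <- stat(roi)
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(n_rand), function(i) stat(sample(roi)),
                       numeric(1))
  list(chisq = unname(observed), df = (nlevels(roi) - 1) * 1,
       p = (1 + sum(null_stats >= observed - 1e-12)) / (n_rand + 1),
       table = table(roi, significant),
       null_stats = null_stats)
}

#' Peak latency of a deconvolved response
#'
#' Before peak detection the coefficient trace is divided by its
#' standard error, attenuating noise-induced peaks in low-precision
#' bins. The electrode must show a significant positive response
#' somewhere in the search window (FDR-corrected p below `alpha`),
#' otherwise the latency is undefined (`NA`) and the electrode is
#' excluded from latency analyses.
#'
#' @param result a `deconv_result`.
#' @param condition condition name.
#' @param search_window window relative to the event alignment point,
#'   ms.
#' @param alpha significance gate on the FDR-corrected p-values.
#' @return latency in ms of the maximum of `coef/se` within the window,
#'   or `NA` if the gate fails or the trace never exceeds zero there.
#' @export
peak_latency <- function(result, condition, search_window = c(0, 500),
                         alpha = 0.05) {
  tr <- get_trace(result, condition)
  if (nrow(tr) == 0) stop("no trace for '", condition, "'", call. = FALSE)
  sel <- tr$time_ms >= search_window[1] & tr$time_ms < search_window[2]
  tr <- tr[sel, ]
  gate <- any(tr$p_fdr < alpha & tr$coef > 0, na.rm = TRUE)
  if (!gate) return(NA_real_)
  snr <- tr$coef / tr$se
  if (all(!is.finite(snr)) || max(snr, na.rm = TRUE) <= 0) return(NA_real_)
  tr$time_ms[which.max(snr)]
}

#' Compare response latencies between two conditions across electrodes
#'
#' Pearson correlation (with its parametric p) of the two latency
#' vectors plus a paired two-sided t-test of their means, over the
#' electrodes with a defined latency for both conditions.
#'
#' @param latency_a,latency_b latency vectors, ms (NA = undefined).
#' @return list with `n`, `r`, `r_p`, `t`, `df`, `t_p`, and per-condition
#'   `mean`/`sd`.
#' @export
latency_comparison <- function(latency_a, latency_b) {
  ok <- is.finite(latency_a) & is.finite(latency_b)
  if (sum(ok) < 3) stop("need at least 3 electrodes with both latencies",
                        call. = FALSE)
  a <- latency_a[ok]; b <- latency_b[ok]
  ct <- cor.test(a, b)
  d <- a - b
  if (sd(d) == 0) {
    # degenerate paired test: all differences identical
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- t.test(a, b, paired = TRUE)
  }
  list(n = sum(ok), r = unname(ct$estimate), r_p = ct$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter),
       t_p = tt$p.value,
       mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b))
}

#' Suppression indices from cross-validated response scalars
#'
#' The saccadic suppression index is
#' `(displacement - saccade) / (displacement + saccade)` and the blink
#' suppression index `(gap - blink) / (gap + blink)`: 0 means identical
#' responses to the external and the self-generated event, 1 means
#' complete suppression of the self-generated transient, and values
#' above 1 are legal when the self-generated response is negative.
#' Indices with a near-zero denominator are flagged undefined and
#' excluded from ROI means.
#'
#' @param scalars tibble with columns `electrode`, `roi`, and the four
#'   response scalars `gap`, `blink`, `displacement`, `saccade` (from
#'   [scalar_response()] on cross-validated estimates).
#' @param tol denominators with absolute value below `tol` yield `NA`.
#' @return list of two tibbles: `electrodes` (per-electrode indices) and
#'   `roi` (ROI mean, SE and n per index).
#' @export
suppression_indices <- function(scalars, tol = 1e-8) {
  idx <- function(ext, self) {
    den <- ext + self
    out <- (ext - self) / den
    out[abs(den) < tol] <- NA_real_
    out
  }
  el <- tibble::tibble(
    electrode = scalars$electrode, roi = scalars$roi,
    blink_index = idx(scalars$gap, scalars$blink),
    saccade_index = idx(scalars$displacement, scalars$saccade))
  n_undef <- sum(is.na(el$blink_index)) + sum(is.na(el$saccade_index))
  if (n_undef > 0)
    message(n_undef, " undefined index value(s) excluded from ROI means")
  roi <- el %>%
    dplyr::group_by(.data$roi) %>%
    dplyr::summarise(
      blink_mean = mean(.data$blink_index, na.rm = TRUE),
      blink_se = sd(.data$blink_index, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$blink_index))),
      saccade_mean = mean(.data$saccade_index, na.rm = TRUE),
      saccade_se = sd(.data$saccade_index, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$saccade_index))),
      n = dplyr::n(), .groups = "drop")
  list(electrodes = el, roi = roi)
}

#' Sorensen-Dice overlap of two significance maps with a permutation test
#'
#' `dice = 2 |A n B| / (|A| + |B|)`. The null permutes one map's labels
#' over the shared electrode universe, preserving the set size, and the
#' p-value is the add-one proportion of null coefficients at or above
#' the observed one.
#'
#' @param set_a,set_b vectors of electrode ids (subsets of `universe`).
#' @param universe all electrode ids shared by the two maps.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return a `dice_result` list: `dice`, `p`, `n_perm`, set sizes.
#' @export
dice_overlap_test <- function(set_a, set_b, universe, n_perm = 100000,
                              seed = NULL) {
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  if (length(set_a) == 0 && length(set_b) == 0)
    stop("both sets empty: Dice coefficient undefined", call. = FALSE)
  dice <- function(a, b) 2 * length(intersect(a, b)) /
    (length(a) + length(b))
  observed <- dice(set_a, set_b)
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i)
    dice(set_a, sample(universe, length(set_b))), numeric(1))
  structure(list(dice = observed,
                 p = (1 + sum(null_stats >= observed - 1e-12)) / (n_perm + 1),
                 n_perm = n_perm, n_a = length(set_a), n_b = length(set_b),
                 n_universe = length(universe)),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> dice = %.4f (|A| = %d, |B| = %d of %d), p = %.3g\n",
              x$dice, x$n_a, x$n_b, x$n_universe, x$p))
  invisible(x)
}

#' Bias-corrected randomization test for a correlation with one outlier
#' removed
#'
#' When a correlation is reported after removing a chosen outlier, its
#' significance cannot be tested against an ordinary shuffle null: the
#' removal is opportunistic and inflates the coefficient. This test
#' builds the null by shuffling `y` against `x` and, in each shuffle,
#' taking the maximum correlation over all possible single-point
#' removals - the same opportunistic advantage the observed statistic
#' enjoyed. The null is therefore centered above zero, and the p-value
#' compares like with like.
#'
#' When the number of distinct permutations `n!` does not exceed
#' `n_shuffle`, all of them are enumerated and the p-value is exact
#' (`#extreme / n!`); otherwise permutations are sampled and the add-one
#' estimator is used.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param designated_outlier index of the point removed in the observed
#'   statistic.
#' @param n_shuffle number of shuffles (or enumeration cap).
#' @param seed RNG seed (ignored when enumerating).
#' @return an `outlier_corr_result` list: `observed_r`, `p`,
#'   `null_center`, `null_stats`, `exhaustive`.
#' @export
outlier_robust_correlation_test <- function(x, y, designated_outlier,
                                            n_shuffle = 10000,
                                            seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4,
            designated_outlier >= 1, designated_outlier <= n)
  if (sd(x[-designated_outlier]) == 0 || sd(y[-designated_outlier]) == 0)
    stop("constant x or y after removal", call. = FALSE)
  observed <- cor(x[-designated_outlier], y[-designated_outlier])
  max_over_removals <- function(yp) {
    max(vapply(seq_len(n), function(i) cor(x[-i], yp[-i]), numeric(1)))
  }
  n_distinct <- factorial(n)
  if (n_distinct <= n_shuffle) {
    perms <- all_permutations(n)
    null_stats <- apply(perms, 1, function(p) max_over_removals(y[p]))
    p <- sum(null_stats >= observed - 1e-12) / n_distinct
    exhaustive <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- vapply(seq_len(n_shuffle), function(i)
      max_over_removals(sample(y)), numeric(1))
    p <- (1 + sum(null_stats >= observed - 1e-12)) / (n_shuffle + 1)
    exhaustive <- FALSE
  }
  structure(list(observed_r = observed, p = p,
                 null_center = mean(null_stats), null_stats = null_stats,
                 exhaustive = exhaustive),
            class = "outlier_corr_result")
}

#' @export
print.outlier_corr_result <- function(x, ...) {
  cat(sprintf("<outlier_corr_result> r = %.3f after designated removal, p = %.4g\n",
              x$observed_r, x$p))
  cat(sprintf("  null of max-over-removals r centered on %.3f (%s)\n",
              x$null_center,
              if (x$exhaustive) "exhaustive" else "sampled"))
  invisible(x)
}

# all n! permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}
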