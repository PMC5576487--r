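#' Within-electrode cluster-area label-shuffle permutation contrast
#'
#' Tests whether one event type's deconvolved HFB contribution carries
#' more positive area than another's. The statistic is
#' `area(largest positive cluster of the positive-condition trace) -
#' area(largest positive cluster of the negative-condition trace)`,
#' computed from the FIR GLM fit. The null distribution reassigns the
#' pooled events of the two conditions to the two labels at random
#' (preserving group sizes) and re-estimates the model for each shuffle;
#' all other conditions stay fixed as nuisance regressors. Both
#' one-sided p-values use the add-one estimator
#' `(1 + #extreme) / (n_perm + 1)`.
#'
#' Refitting uses an algebraically exact shortcut: the nuisance set is
#' partialled out of the recording and of the two shuffled FIR sets once
#' (Frisch-Waugh-Lovell), so each shuffle only solves the two sets'
#' reduced normal equations. [contrast_stat_full_refit()] provides the
#' literal full-model refit for verification.
#'
#' @param y numeric trace or [hfb_recording()] (with `electrode`).
#' @param events event tibble.
#' @param spec a [design_spec()] describing every modeled condition.
#' @param n_samples recording length in samples (taken from `y` when it
#'   is a recording).
#' @param fs sampling rate, Hz.
#' @param mask optional [rejection_mask()].
#' @param cond_pos condition (prefix) whose events form the
#'   positive-labeled group, e.g. `"displacement"`.
#' @param cond_neg condition of the negative-labeled group, e.g.
#'   `"saccade_in_range"`.
#' @param n_perm number of label shuffles.
#' @param seed RNG seed for the shuffles.
#' @param electrode electrode id/index when `y` is a recording.
#' @return a `perm_test_result`: `observed_stat`, `null_stats`,
#'   `p_pos_gt_neg`, `p_neg_gt_pos`, group sizes, and the observed
#'   condition traces. `NULL` (with a warning) when either group has
#'   fewer than 2 events.
#' @export
cluster_area_perm_test <- function(y, events, spec, n_samples = NULL,
                                   fs = NULL, mask = NULL,
                                   cond_pos = "displacement",
                                   cond_neg = "saccade_in_range",
                                   n_perm = 10000, seed = NULL,
                                   electrode = 1L) {
  if (inherits(y, "hfb_recording")) {
    if (is.null(fs)) fs <- y$fs
    n_samples <- n_samples %||% nrow(y$data)
    y <- electrode_trace(y, electrode)
  }
  n_samples <- n_samples %||% length(y)
  eng <- contrast_engine(y, events, spec, n_samples, fs, mask,
                         cond_pos, cond_neg)
  if (is.null(eng)) return(NULL)
  if (!is.null(seed)) set.seed(seed)
  obs <- contrast_fit(eng, eng$g_obs)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    contrast_fit(eng, sample(eng$g_obs))$stat
  }, numeric(1))
  structure(list(
    observed_stat = obs$stat,
    null_stats = null_stats,
    p_pos_gt_neg = (1 + sum(null_stats >= obs$stat)) / (n_perm + 1),
    p_neg_gt_pos = (1 + sum(null_stats <= obs$stat)) / (n_perm + 1),
    n_pos = sum(eng$g_obs == 1L), n_neg = sum(eng$g_obs == 2L),
    n_perm = n_perm,
    trace_pos = obs$beta_pos, trace_neg = obs$beta_neg,
    lags_ms = eng$lags_ms,
    cond_pos = cond_pos, cond_neg = cond_neg),
    class = "perm_test_result")
}

#' @rdname cluster_area_perm_test
#' @param ... passed to [cluster_area_perm_test()].
#' @export
displacement_vs_saccade_perm_test <- function(y, events, spec, ...) {
  cluster_area_perm_test(y, events, spec, cond_pos = "displacement",
                         cond_neg = "saccade_in_range", ...)
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("<perm_test_result> %s vs %s: stat = %.2f SD*ms\n",
              x$cond_pos, x$cond_neg, x$observed_stat))
  cat(sprintf("  p(%s > %s) = %.4g, p(%s > %s) = %.4g (%d shuffles)\n",
              x$cond_pos, x$cond_neg, x$p_pos_gt_neg,
              x$cond_neg, x$cond_pos, x$p_neg_gt_pos, x$n_perm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- internal machinery -------------------------------------------------

event_matches <- function(condition, cond) {
  condition == cond | startsWith(condition, paste0(cond, "_"))
}

# Precompute everything that does not depend on the label assignment.
contrast_engine <- function(y, events, spec, n_samples, fs, mask,
                            cond_pos, cond_neg) {
  ev <- events[!events$excluded %in% TRUE, ]
  is_pos <- event_matches(ev$condition, cond_pos)
  is_neg <- event_matches(ev$condition, cond_neg)
  if (sum(is_pos) < 2 || sum(is_neg) < 2) {
    warning("fewer than 2 events in a group; test skipped")
    return(NULL)
  }
  target <- ev[is_pos | is_neg, ]
  g_obs <- ifelse(event_matches(target$condition, cond_pos), 1L, 2L)

  # shared FIR window of the two sets, from the spec
  sn <- match_spec_condition(target$condition[1], names(spec$conditions))
  entry <- spec$conditions[[sn]]
  lags_ms <- seq(entry$window[1], entry$window[2] - spec$bin_ms,
                 by = spec$bin_ms)
  lag_smp <- round(lags_ms / 1000 * fs)
  K <- length(lag_smp)

  # nuisance design: every spec condition not in the shuffled pair
  nuis_spec <- spec
  target_entries <- unique(match_spec_condition(target$condition,
                                                names(spec$conditions)))
  nuis_spec$conditions <-
    spec$conditions[!names(spec$conditions) %in% target_entries]
  nuis_ev <- ev[!(is_pos | is_neg), ]
  rows_ok <- rep(TRUE, n_samples)
  if (!is.null(mask)) rows_ok <- !mask_samples(mask, n_samples, fs)
  rows_ok <- rows_ok & is.finite(y)
  if (length(nuis_spec$conditions) && nrow(nuis_ev)) {
    Dn <- suppressWarnings(
      build_design_matrix(nuis_ev, nuis_spec, n_samples, fs, mask = NULL))
    Nmat <- cbind(Matrix::sparseMatrix(i = seq_len(n_samples),
                                       j = rep(1L, n_samples), x = 1,
                                       dims = c(n_samples, 1L)),
                  Dn$X)[rows_ok, , drop = FALSE]
  } else {
    Nmat <- Matrix::sparseMatrix(i = seq_len(n_samples),
                                 j = rep(1L, n_samples), x = 1,
                                 dims = c(n_samples, 1L))[rows_ok, ,
                                                          drop = FALSE]
  }
  # drop all-zero nuisance columns (events fully masked/truncated away)
  nz <- Matrix::colSums(Nmat != 0) > 0
  Nmat <- Nmat[, nz, drop = FALSE]

  ys <- y[rows_ok]
  rowpos <- cumsum(rows_ok)          # original sample -> retained row

  align <- if (entry$align == "onset") target$onset_ms else target$offset_ms
  a <- round(align / 1000 * fs) + 1L
  m <- nrow(target)
  rows <- outer(a, lag_smp, `+`)                       # m x K
  colk <- matrix(rep(seq_len(K), each = m), nrow = m)  # lag index
  cole <- matrix(rep(seq_len(m), K), nrow = m)         # event index
  ok <- rows >= 1L & rows <= n_samples
  ok[ok] <- rows_ok[rows[ok]]
  A <- Matrix::sparseMatrix(i = rowpos[rows[ok]],
                            j = (cole[ok] - 1L) * K + colk[ok],
                            x = 1, dims = c(length(ys), m * K))
  NtN <- as.matrix(Matrix::crossprod(Nmat))
  chN <- chol(NtN)
  Nty <- as.numeric(Matrix::crossprod(Nmat, ys))
  v <- backsolve(chN, forwardsolve(t(chN), Nty))   # (N'N)^-1 N'y

  # Everything that varies across shuffles is a relabeling of events, so
  # the per-(event-pair, lag-pair) Gram contributions are precomputed as
  # sparse matrices over lag indices x event(-pair) indices; one shuffle
  # then reduces to two small indicator GEMMs and one solve.
  AtA <- methods::as(methods::as(Matrix::crossprod(A), "generalMatrix"),
                     "TsparseMatrix")
  r_ix <- AtA@i; c_ix <- AtA@j               # 0-based (event,lag) columns
  re <- r_ix %/% K + 1L; rk <- r_ix %% K + 1L
  ce <- c_ix %/% K + 1L; ck <- c_ix %% K + 1L
  key <- (re - 1L) * m + ce
  up <- sort(unique(key))
  pidx <- match(key, up)
  B <- Matrix::sparseMatrix(i = (ck - 1L) * K + rk, j = pidx, x = AtA@x,
                            dims = c(K * K, length(up)))
  NtA <- methods::as(Matrix::crossprod(Nmat, A), "TsparseMatrix")
  q <- nrow(NtA)
  Bn <- Matrix::sparseMatrix(i = (NtA@j %% K) * q + NtA@i + 1L,
                             j = NtA@j %/% K + 1L, x = NtA@x,
                             dims = c(q * K, m))
  Aty <- matrix(as.numeric(Matrix::crossprod(A, ys)), nrow = K)
  list(B = B, pair_re = (up - 1L) %/% m + 1L, pair_ce = (up - 1L) %% m + 1L,
       n_pair = length(up), Bn = Bn,
       q = q, chN = chN, tchN = t(chN), v = v,
       Aty = Aty, K = K, m = m, lags_ms = lags_ms,
       bin_ms = spec$bin_ms, g_obs = g_obs)
}

# area of the largest strictly-positive run (fast path, no bookkeeping)
cluster_area_max <- function(x, bin_ms) {
  r <- rle(x > 0)
  if (!any(r$values)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(x))
  max((cs[ends + 1L] - cs[starts])[r$values]) * bin_ms
}

# Solve the partialled normal equations for one label assignment and
# return the cluster-area statistic.
contrast_fit <- function(eng, g) {
  K <- eng$K
  P <- 2L * K
  blk <- g[eng$pair_re] + 2L * (g[eng$pair_ce] - 1L)
  Mp <- matrix(0, eng$n_pair, 4L)
  Mp[cbind(seq_len(eng$n_pair), blk)] <- 1
  XB <- as.matrix(eng$B %*% Mp)              # K^2 x 4 block stack
  XtX <- matrix(0, P, P)
  i1 <- seq_len(K); i2 <- K + i1
  XtX[i1, i1] <- XB[, 1]; XtX[i2, i1] <- XB[, 2]
  XtX[i1, i2] <- XB[, 3]; XtX[i2, i2] <- XB[, 4]
  Mg <- matrix(0, eng$m, 2L)
  Mg[cbind(seq_len(eng$m), g)] <- 1
  NX <- as.matrix(eng$Bn %*% Mg)             # (q*K) x 2
  NtX <- cbind(matrix(NX[, 1], eng$q, K), matrix(NX[, 2], eng$q, K))
  W <- forwardsolve(eng$tchN, NtX)           # R^-T N'X; correction = W'W
  G <- XtX - crossprod(W)
  AtyM <- eng$Aty %*% Mg
  rhs <- c(AtyM[, 1], AtyM[, 2]) - as.numeric(crossprod(NtX, eng$v))
  ch <- tryCatch(chol(G), error = function(e) NULL)
  beta <- if (!is.null(ch)) {
    backsolve(ch, forwardsolve(t(ch), rhs))
  } else suppressWarnings(solve_gram(G, rhs))$beta
  bp <- beta[seq_len(K)]
  bn <- beta[K + seq_len(K)]
  stat <- cluster_area_max(bp, eng$bin_ms) -
    cluster_area_max(bn, eng$bin_ms)
  list(stat = stat, beta_pos = bp, beta_neg = bn)
}

#' Cluster-area contrast statistic by literal full-model refit
#'
#' Rebuilds the complete design with the two contrasted sets relabeled
#' according to `assignment` and fits the full FIR GLM. Exists to verify
#' that the partialled fast path used by [cluster_area_perm_test()] is
#' algebraically identical to the literal full-model refit.
#'
#' @inheritParams cluster_area_perm_test
#' @param assignment integer vector over the pooled events of the two
#'   conditions (in event-table order): 1 = positive label, 2 = negative.
#' @return list with `stat`, `beta_pos`, `beta_neg`.
#' @export
contrast_stat_full_refit <- function(y, events, spec, n_samples, fs,
                                     mask = NULL,
                                     cond_pos = "displacement",
                                     cond_neg = "saccade_in_range",
                                     assignment = NULL) {
  ev <- events[!events$excluded %in% TRUE, ]
  sel <- event_matches(ev$condition, cond_pos) |
    event_matches(ev$condition, cond_neg)
  if (is.null(assignment))
    assignment <- ifelse(event_matches(ev$condition[sel], cond_pos), 1L, 2L)
  orig_conds <- unique(events$condition[event_matches(events$condition,
                                                      cond_pos) |
                                          event_matches(events$condition,
                                                        cond_neg)])
  target_entries <- unique(match_spec_condition(orig_conds,
                                                names(spec$conditions)))
  entry <- spec$conditions[[target_entries[1]]]
  spec2 <- spec
  spec2$conditions <- c(
    spec$conditions[!names(spec$conditions) %in% target_entries],
    list(.pos = entry, .neg = entry))
  ev$condition[sel] <- c(".pos", ".neg")[assignment]
  D <- suppressWarnings(build_design_matrix(ev, spec2, n_samples, fs, mask))
  fit <- suppressWarnings(fit_fir_glm(y, D))
  bp <- get_trace(fit, ".pos")$coef
  bn <- get_trace(fit, ".neg")$coef
  lags_ms <- get_trace(fit, ".pos")$time_ms
  stat <- largest_positive_cluster(bp, spec$bin_ms, lags_ms)$area -
    largest_positive_cluster(bn, spec$bin_ms, lags_ms)$area
  list(stat = stat, beta_pos = bp, beta_neg = bn)
}

#' FDR correction of permutation p-values across electrodes
#'
#' Benjamini-Hochberg applied separately to each one-sided family
#' (positive-greater and negative-greater), mirroring the two corrected
#' columns of the electrode-level statistical map.
#'
#' @param results list of `perm_test_result` objects (NULL entries,
#'   from skipped electrodes, are dropped).
#' @param electrodes optional electrode ids.
#' @return tibble with `electrode`, `observed_stat`, `p_pos_gt_neg`,
#'   `p_neg_gt_pos`, `q_pos_gt_neg`, `q_neg_gt_pos`.
#' @export
fdr_across_electrodes <- function(results, electrodes = NULL) {
  if (is.null(electrodes)) electrodes <- sprintf("e%03d", seq_along(results))
  keep <- !vapply(results, is.null, logical(1))
  results <- results[keep]
  out <- tibble::tibble(
    electrode = electrodes[keep],
    observed_stat = unname(vapply(results, `[[`, numeric(1),
                                  "observed_stat")),
    p_pos_gt_neg = unname(vapply(results, `[[`, numeric(1),
                                 "p_pos_gt_neg")),
    p_neg_gt_pos = unname(vapply(results, `[[`, numeric(1),
                                 "p_neg_gt_pos")))
  out$q_pos_gt_neg <- p.adjust(out$p_pos_gt_neg, method = "BH")
  out$q_neg_gt_pos <- p.adjust(out$p_neg_gt_pos, method = "BH")
  out
}
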