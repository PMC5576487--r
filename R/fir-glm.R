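#' Fit the FIR GLM by ordinary least squares
#'
#' Estimates every condition's deconvolved response trace jointly, with a
#' per-recording intercept, by solving the normal equations of the
#' indicator design. Each coefficient is the unique contribution of its
#' condition at its lag, in the units of the recording (baseline SDs).
#' Standard errors come from the residual variance and the diagonal of
#' the Gram inverse; per-timepoint two-sided p-values are
#' Benjamini-Hochberg corrected across all coefficients of the
#' electrode. A rank-deficient design falls back to the minimum-norm
#' solution with the affected lags flagged.
#'
#' @param y numeric trace (one electrode, analysis rate), or an
#'   [hfb_recording()] together with `electrode`.
#' @param design a [build_design_matrix()] result.
#' @param electrode electrode id/index when `y` is a recording.
#' @return a `deconv_result`: tibble `trace` (`condition`, `time_ms`,
#'   `coef`, `se`, `p`, `p_fdr`, `estimable`) plus `intercept`,
#'   `sigma2`, `df`, `n_events`, `rank_deficient`.
#' @export
fit_fir_glm <- function(y, design, electrode = 1L) {
  if (inherits(y, "hfb_recording")) {
    rows_valid <- y$validity
    y <- electrode_trace(y, electrode)
  } else rows_valid <- rep(TRUE, length(y))
  stopifnot(inherits(design, "fir_design"),
            length(y) == nrow(design$X))
  rows <- design$valid_rows & rows_valid & is.finite(y)
  Xs <- design$X[rows, , drop = FALSE]
  ys <- y[rows]
  nr <- length(ys)
  p <- ncol(Xs)
  if (nr <= p + 1) stop("fewer retained samples than predictors",
                        call. = FALSE)
  XtX <- as.matrix(Matrix::crossprod(Xs))
  cs <- Matrix::colSums(Xs)
  G <- rbind(c(nr, cs), cbind(cs, XtX))
  b <- c(sum(ys), as.numeric(Matrix::crossprod(Xs, ys)))
  sol <- solve_gram(G, b)
  beta <- sol$beta
  fitted <- as.numeric(Xs %*% beta[-1]) + beta[1]
  rss <- sum((ys - fitted)^2)
  df <- nr - sol$rank
  sigma2 <- rss / df
  se <- sqrt(sigma2 * sol$ginv_diag)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  trace <- design$col_map
  trace$coef <- beta[-1]
  trace$se <- se[-1]
  trace$p <- pval[-1]
  trace$p_fdr <- p.adjust(pval[-1], method = "BH")
  trace$estimable <- sol$estimable[-1]
  names(trace)[names(trace) == "lag_ms"] <- "time_ms"
  structure(list(trace = trace[, c("condition", "time_ms", "coef", "se",
                                   "p", "p_fdr", "estimable")],
                 intercept = beta[1], sigma2 = sigma2, df = df,
                 n_events = design$n_events,
                 rank_deficient = sol$rank_deficient),
            class = "deconv_result")
}

# Cholesky solve of the normal equations with a minimum-norm
# (pseudo-inverse) fallback for rank-deficient Gram matrices
solve_gram <- function(G, b) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(ch)) {
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    ginv_diag <- diag(chol2inv(ch))
    return(list(beta = beta, ginv_diag = ginv_diag, rank = ncol(G),
                estimable = rep(TRUE, ncol(G)), rank_deficient = FALSE))
  }
  warning("rank-deficient design: minimum-norm solution, ",
          "inestimable lags flagged")
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(eg$values) * ncol(G) * .Machine$double.eps
  pos <- eg$values > tol
  vinv <- ifelse(pos, 1 / eg$values, 0)
  Ginv <- eg$vectors %*% (vinv * t(eg$vectors))
  beta <- as.numeric(Ginv %*% b)
  # a coefficient is estimable iff its unit vector lies in the row space
  nullspace <- eg$vectors[, !pos, drop = FALSE]
  estimable <- rowSums(nullspace^2) < 1e-8
  list(beta = beta, ginv_diag = pmax(diag(Ginv), 0), rank = sum(pos),
       estimable = estimable, rank_deficient = TRUE)
}

#' @export
print.deconv_result <- function(x, ...) {
  nev <- paste(sprintf("%s: %d", names(x$n_events),
                       unlist(x$n_events)), collapse = ", ")
  cat(sprintf("<deconv_result> %d coefficients, sigma^2 = %.3f, df = %d\n",
              nrow(x$trace), x$sigma2, x$df))
  cat("  events -", nev, "\n")
  invisible(x)
}

#' Extract one condition's deconvolved trace
#'
#' @param result a `deconv_result` or `cv_deconv_result`.
#' @param condition condition name.
#' @return tibble subset of the trace for that condition.
#' @export
get_trace <- function(result, condition) {
  tr <- result$trace
  tr[tr$condition == condition, , drop = FALSE]
}

#' Cross-validated deconvolution estimates
#'
#' Blocks are partitioned into folds; for each fold the GLM is refit with
#' the held-out blocks' samples removed, giving coefficient estimates
#' statistically independent of the held-out data. The combined estimate
#' is the mean of the per-fold traces. These are the estimates that feed
#' the suppression-index scalars, so that index numerators and
#' denominators are not reused from the selection step.
#'
#' @param y trace or [hfb_recording()] (see [fit_fir_glm()]).
#' @param design a `fir_design`.
#' @param blocks block layout tibble (`block`, `start_ms`, `end_ms`),
#'   e.g. `attr(schedule, "blocks")`.
#' @param n_folds number of folds (blocks split round-robin).
#' @param pad_ms samples within this margin of a held-out block are also
#'   held out, covering FIR windows that straddle block edges.
#' @param electrode electrode id/index when `y` is a recording.
#' @return a `cv_deconv_result`: combined `trace` tibble (`condition`,
#'   `time_ms`, `coef`, `n_folds_used`) and the per-fold results.
#' @export
crossvalidated_estimates <- function(y, design, blocks, n_folds = 5,
                                     pad_ms = 500, electrode = 1L) {
  if (inherits(y, "hfb_recording")) y <- electrode_trace(y, electrode)
  n_folds <- min(n_folds, nrow(blocks))
  fold_of <- ((seq_len(nrow(blocks)) - 1L) %% n_folds) + 1L
  n <- nrow(design$X)
  fs <- design$fs
  fold_fits <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- blocks[fold_of == f, ]
    drop <- rep(FALSE, n)
    for (i in seq_len(nrow(held))) {
      j0 <- max(1L, floor((held$start_ms[i] - pad_ms) / 1000 * fs) + 1L)
      j1 <- min(n, ceiling((held$end_ms[i] + pad_ms) / 1000 * fs))
      drop[j0:j1] <- TRUE
    }
    d2 <- design
    d2$valid_rows <- design$valid_rows & !drop
    # conditions with no remaining events cannot be estimated in this fold
    a_ms <- alignment_ms(d2$events)
    in_train <- !drop[pmin(pmax(round(a_ms / 1000 * fs) + 1L, 1L), n)]
    missing <- setdiff(unique(d2$events$model_condition),
                       unique(d2$events$model_condition[in_train]))
    keep_cols <- !d2$col_map$condition %in% missing
    if (length(missing)) {
      message("fold ", f, ": dropping condition(s) with no training events: ",
              paste(missing, collapse = ", "))
      d2$X <- d2$X[, keep_cols, drop = FALSE]
      d2$col_map <- d2$col_map[keep_cols, ]
      d2$col_map$col <- seq_len(nrow(d2$col_map))
    }
    fold_fits[[f]] <- suppressWarnings(fit_fir_glm(y, d2))
  }
  combined <- dplyr::bind_rows(lapply(fold_fits, function(r)
    r$trace[, c("condition", "time_ms", "coef")])) %>%
    dplyr::group_by(.data$condition, .data$time_ms) %>%
    dplyr::summarise(n_folds_used = dplyr::n(), coef = mean(.data$coef),
                     .groups = "drop") %>%
    dplyr::arrange(match(.data$condition, unique(design$col_map$condition)),
                   .data$time_ms)
  structure(list(trace = combined, folds = fold_fits, n_folds = n_folds),
            class = "cv_deconv_result")
}

#' Scalar response magnitude of a deconvolved trace
#'
#' The mean of the coefficient trace over a post-event window; used as
#' the "HFB increase" scalar entering the suppression indices.
#'
#' @param result a `deconv_result` or `cv_deconv_result` (or a tibble
#'   with `condition`, `time_ms`, `coef`).
#' @param condition condition name.
#' @param window post-event window, ms (must lie inside the FIR window).
#' @return scalar mean response.
#' @export
scalar_response <- function(result, condition, window = c(0, 500)) {
  tr <- if (is.data.frame(result)) {
    result[result$condition == condition, ]
  } else get_trace(result, condition)
  if (nrow(tr) == 0)
    stop("no trace for condition '", condition, "'", call. = FALSE)
  sel <- tr$time_ms >= window[1] & tr$time_ms < window[2]
  if (!any(sel)) stop("empty scalar window", call. = FALSE)
  mean(tr$coef[sel])
}

#' Naive event-locked average
#'
#' Plain mean across events of the trace aligned to the events'
#' alignment points, with no overlap correction. Provided to demonstrate
#' the overlap bias that the FIR GLM removes.
#'
#' @param y numeric trace.
#' @param events event tibble.
#' @param condition condition (prefix) selecting the events.
#' @param window window relative to the alignment point, ms.
#' @param fs sampling rate, Hz.
#' @param align `"onset"`, `"offset"`, or `NULL` to use the stimulus /
#'   non-stimulus convention.
#' @return tibble with `time_ms` and `mean`.
#' @export
event_locked_average <- function(y, events, condition, window = c(0, 500),
                                 fs = 100, align = NULL) {
  ev <- events[startsWith(events$condition, condition) &
                 !events$excluded %in% TRUE, ]
  if (nrow(ev) == 0) stop("no events of condition '", condition, "'",
                          call. = FALSE)
  a_ms <- if (is.null(align)) alignment_ms(ev)
          else if (align == "onset") ev$onset_ms else ev$offset_ms
  lag_smp <- seq(round(window[1] / 1000 * fs),
                 round(window[2] / 1000 * fs) - 1L)
  a <- round(a_ms / 1000 * fs) + 1L
  segs <- vapply(a, function(ai) {
    idx <- ai + lag_smp
    out <- rep(NA_real_, length(lag_smp))
    ok <- idx >= 1 & idx <= length(y)
    out[ok] <- y[idx[ok]]
    out
  }, numeric(length(lag_smp)))
  tibble::tibble(time_ms = lag_smp / fs * 1000,
                 mean = rowMeans(segs, na.rm = TRUE))
}
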