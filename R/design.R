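#' FIR design specification
#'
#' Defines, per condition, the FIR window relative to the alignment point
#' and the alignment rule. Displacement, saccade, blink and gap responses
#' are aligned to event offsets with a window from 300 ms before to
#' 500 ms after; stimulus responses are aligned to onsets. The bin width
#' must match the analysis sampling period (one coefficient per sample).
#'
#' Condition entries match event conditions by name or by prefix, so a
#' single `displacement` entry pools `displacement_small` and
#' `displacement_large` into one predictor set, while separate entries
#' keep them apart.
#'
#' @param bin_ms FIR bin width, ms.
#' @param pool_displacements model both displacement magnitudes with a
#'   single predictor set (as in the electrode-level statistical map)
#'   instead of separate sets.
#' @param event_window FIR window for displacement/saccade/blink/gap
#'   sets, ms relative to the event offset.
#' @param stimulus_window FIR window for stimulus sets, ms relative to
#'   onset.
#' @param conditions optional fully explicit condition list; overrides
#'   the arguments above. Each element must be
#'   `list(window = c(start, end), align = "onset"|"offset")`.
#' @return a `design_spec` object.
#' @export
design_spec <- function(bin_ms = 10, pool_displacements = FALSE,
                        event_window = c(-300, 500),
                        stimulus_window = c(0, 500),
                        conditions = NULL) {
  if (is.null(conditions)) {
    ev <- list(window = event_window, align = "offset")
    st <- list(window = stimulus_window, align = "onset")
    conditions <- list(stimulus_face = st, stimulus_nonface = st,
                       saccade_in_range = ev, saccade_below = ev,
                       saccade_above = ev, blink = ev, gap = ev)
    if (pool_displacements) {
      conditions$displacement <- ev
    } else {
      conditions$displacement_small <- ev
      conditions$displacement_large <- ev
    }
  }
  for (cn in names(conditions)) {
    w <- conditions[[cn]]$window
    if (w[1] >= w[2]) stop("window start must precede end", call. = FALSE)
    if (abs((w[2] - w[1]) %% bin_ms) > 1e-9)
      stop("bin width must divide the window length", call. = FALSE)
    if (!conditions[[cn]]$align %in% c("onset", "offset"))
      stop("align must be 'onset' or 'offset'", call. = FALSE)
  }
  structure(list(bin_ms = bin_ms, conditions = conditions),
            class = "design_spec")
}

# map an event condition to its spec entry name (exact, then prefix)
match_spec_condition <- function(event_cond, spec_names) {
  hit <- match(event_cond, spec_names)
  miss <- is.na(hit)
  if (any(miss)) {
    for (i in which(miss)) {
      pre <- spec_names[startsWith(event_cond[i], spec_names)]
      if (length(pre)) hit[i] <- match(pre[which.max(nchar(pre))], spec_names)
    }
  }
  ifelse(is.na(hit), NA_character_, spec_names[hit])
}

#' Build the sparse FIR design matrix
#'
#' For each event of condition `c` and each lag in `c`'s window, a 1 is
#' placed at sample `alignment + lag`. Lags that would fall outside the
#' recording are truncated (the affected coefficients are still
#' estimated from the remaining events) with a warning. Samples covered
#' by the rejection mask are flagged invalid and excluded from fits.
#'
#' @param events event tibble (rows with `excluded = TRUE` are dropped;
#'   event conditions without a matching spec entry are ignored with a
#'   warning).
#' @param spec a [design_spec()].
#' @param n_samples recording length in samples.
#' @param fs sampling rate, Hz; must equal `1000 / spec$bin_ms`.
#' @param mask optional [rejection_mask()].
#' @return a `fir_design`: sparse matrix `X` (`n_samples` x predictors),
#'   `col_map` tibble (`col`, `condition`, `lag_ms`), `valid_rows`
#'   logical, `n_events` per modeled condition, and the events used.
#' @export
build_design_matrix <- function(events, spec, n_samples, fs, mask = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (abs(1000 / fs - spec$bin_ms) > 1e-9)
    stop("bin width must equal the sampling period", call. = FALSE)
  ev <- events[!events$excluded %in% TRUE, ]
  ev$model_condition <- match_spec_condition(ev$condition,
                                             names(spec$conditions))
  unmatched <- unique(ev$condition[is.na(ev$model_condition)])
  if (length(unmatched))
    warning("no predictor set for condition(s): ",
            paste(unmatched, collapse = ", "))
  ev <- ev[!is.na(ev$model_condition), ]
  conds <- intersect(names(spec$conditions), unique(ev$model_condition))

  ii <- jj <- list()
  col_map <- list()
  col0 <- 0L
  truncated <- FALSE
  for (cn in conds) {
    w <- spec$conditions[[cn]]$window
    lags_ms <- seq(w[1], w[2] - spec$bin_ms, by = spec$bin_ms)
    lag_smp <- round(lags_ms / 1000 * fs)
    e <- ev[ev$model_condition == cn, ]
    align_ms <- if (spec$conditions[[cn]]$align == "onset") e$onset_ms else e$offset_ms
    a <- round(align_ms / 1000 * fs) + 1L
    rows <- outer(a, lag_smp, `+`)
    cols <- matrix(rep(col0 + seq_along(lag_smp), each = nrow(e)),
                   nrow = nrow(e))
    ok <- rows >= 1L & rows <= n_samples
    if (!all(ok)) truncated <- TRUE
    ii[[cn]] <- rows[ok]
    jj[[cn]] <- cols[ok]
    col_map[[cn]] <- tibble::tibble(col = col0 + seq_along(lag_smp),
                                    condition = cn, lag_ms = lags_ms)
    col0 <- col0 + length(lag_smp)
  }
  if (truncated)
    warning("event window(s) extend past the recording; truncated")
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = 1, dims = c(n_samples, col0))
  valid_rows <- rep(TRUE, n_samples)
  if (!is.null(mask)) valid_rows <- !mask_samples(mask, n_samples, fs)
  n_events <- table(factor(ev$model_condition, levels = conds))
  structure(list(X = X, col_map = dplyr::bind_rows(col_map),
                 valid_rows = valid_rows, fs = fs, spec = spec,
                 n_events = as.list(n_events), events = ev),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("<fir_design> %d samples x %d predictors, %d condition sets\n",
              nrow(x$X), ncol(x$X), length(unique(x$col_map$condition))))
  invisible(x)
}
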