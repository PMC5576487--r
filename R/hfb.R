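#' Analytic-signal amplitude (envelope) of a real signal
#'
#' Standard FFT construction of the analytic signal: double the
#' positive-frequency coefficients, zero the negative ones, inverse
#' transform, take the modulus.
#'
#' @param x real numeric vector.
#' @return non-negative envelope, same length as `x`.
#' @keywords internal
analytic_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Estimate the high-frequency broadband (HFB) envelope
#'
#' The 70--150 Hz band is split into 10-Hz sub-bands; each sub-band is
#' band-pass filtered (zero-phase Butterworth), its analytic-signal
#' amplitude taken and divided by its own recording mean so that each
#' sub-band contributes equally despite the 1/f spectrum; the normalized
#' amplitudes are averaged, decimated to the analysis rate by
#' non-overlapping window means (which keeps event alignment within one
#' analysis sample), and z-scored against baseline samples.
#'
#' @param raw numeric matrix (samples x electrodes) or vector of raw
#'   voltage traces.
#' @param fs sampling rate of `raw`, Hz (must exceed twice the band top).
#' @param band HFB band edges, Hz.
#' @param subband_width sub-band width, Hz.
#' @param analysis_rate output rate, Hz; `fs / analysis_rate` must be a
#'   whole number.
#' @param baseline logical vector at the analysis rate marking baseline
#'   samples (e.g. inter-block gray periods), or `NULL` to z-score
#'   against the whole recording.
#' @param filter_order Butterworth order per pass.
#' @param electrodes optional electrode metadata tibble.
#' @return an [hfb_recording()] at `analysis_rate` in baseline-SD units.
#' @export
estimate_hfb <- function(raw, fs, band = c(70, 150), subband_width = 10,
                         analysis_rate = 100, baseline = NULL,
                         filter_order = 4, electrodes = NULL) {
  if (is.vector(raw)) raw <- matrix(raw, ncol = 1)
  if (band[2] >= fs / 2)
    stop("band extends to or beyond the Nyquist frequency", call. = FALSE)
  factor <- fs / analysis_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs must be an integer multiple of analysis_rate", call. = FALSE)
  factor <- round(factor)
  lo <- seq(band[1], band[2] - subband_width, by = subband_width)
  env <- matrix(0, nrow(raw), ncol(raw))
  for (l in lo) {
    bf <- signal::butter(filter_order, c(l, l + subband_width) / (fs / 2),
                         type = "pass")
    for (e in seq_len(ncol(raw))) {
      a <- analytic_envelope(signal::filtfilt(bf, raw[, e]))
      env[, e] <- env[, e] + a / mean(a)
    }
  }
  env <- env / length(lo)
  dec <- decimate_mean(env, factor)
  if (is.null(baseline)) baseline <- rep(TRUE, nrow(dec))
  stopifnot(length(baseline) == nrow(dec), sum(baseline) >= 2)
  for (e in seq_len(ncol(dec))) {
    mu <- mean(dec[baseline, e]); s <- sd(dec[baseline, e])
    dec[, e] <- (dec[, e] - mu) / s
  }
  hfb_recording(dec, fs = analysis_rate, electrodes = electrodes)
}

#' Envelope of one HFB sub-band
#'
#' Band-pass filters a single sub-band and returns its analytic
#' amplitude (no normalization); mainly useful for validating the
#' envelope step against known signals.
#'
#' @inheritParams estimate_hfb
#' @param x numeric vector.
#' @return non-negative envelope of the filtered signal.
#' @export
subband_envelope <- function(x, fs, band, filter_order = 4) {
  bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  analytic_envelope(signal::filtfilt(bf, x))
}

# non-overlapping boxcar decimation; drops a ragged tail
decimate_mean <- function(x, factor) {
  if (factor == 1) return(x)
  m <- floor(nrow(x) / factor)
  idx <- rep(seq_len(m), each = factor)
  out <- apply(x[seq_len(m * factor), , drop = FALSE], 2, function(col)
    as.numeric(tapply(col, idx, mean)))
  matrix(out, nrow = m)
}

#' Screen electrodes for visual responsiveness
#'
#' For each electrode, per-trial mean HFB in a response window after
#' stimulus onset is compared against per-trial mean HFB in a baseline
#' window by a two-sided paired t-test. P-values are Bonferroni-corrected
#' across the electrodes tested together (within subject), and an
#' electrode is included iff the corrected p falls below `alpha` AND its
#' effect size (mean response-window HFB, in baseline-SD units) is at
#' least `effect_min`.
#'
#' @param hfb an [hfb_recording()].
#' @param stimulus_events event tibble; rows whose condition starts with
#'   `"stimulus"` define the trials (excluded trials are dropped).
#' @param response_window window relative to stimulus onset, ms.
#' @param baseline_window window relative to stimulus onset, ms (negative
#'   = pre-onset; within blocks this still contains the previous trial's
#'   tail, which only makes the test conservative).
#' @param alpha significance level before correction.
#' @param effect_min minimum effect size in baseline-SD units.
#' @param n_comparisons Bonferroni divisor; defaults to the number of
#'   electrodes in `hfb`.
#' @return tibble with `electrode`, `p`, `p_bonf`, `effect_size`,
#'   `included`.
#' @export
screen_visual_responsiveness <- function(hfb, stimulus_events,
                                         response_window = c(50, 450),
                                         baseline_window = c(-300, 0),
                                         alpha = 0.05, effect_min = 2,
                                         n_comparisons = ncol(hfb$data)) {
  ev <- stimulus_events[startsWith(stimulus_events$condition, "stimulus") &
                          !stimulus_events$excluded %in% TRUE, ]
  if (nrow(ev) < 2) stop("need at least two stimulus events", call. = FALSE)
  if (diff(response_window) <= 0 || diff(baseline_window) <= 0)
    stop("empty response or baseline window", call. = FALSE)
  fs <- hfb$fs
  n <- nrow(hfb$data)
  win_idx <- function(onset, w) {
    j <- (round(onset / 1000 * fs) + 1L) +
      seq(floor(w[1] / 1000 * fs), ceiling(w[2] / 1000 * fs) - 1L)
    j[j >= 1 & j <= n]
  }
  resp_idx <- lapply(ev$onset_ms, win_idx, w = response_window)
  base_idx <- lapply(ev$onset_ms, win_idx, w = baseline_window)
  ok <- lengths(resp_idx) > 0 & lengths(base_idx) > 0
  out <- lapply(seq_len(ncol(hfb$data)), function(e) {
    tr <- hfb$data[, e]
    r <- vapply(resp_idx[ok], function(j) mean(tr[j]), numeric(1))
    b <- vapply(base_idx[ok], function(j) mean(tr[j]), numeric(1))
    tt <- t.test(r, b, paired = TRUE)
    tibble::tibble(electrode = hfb$electrodes$electrode[e],
                   p = tt$p.value, effect_size = mean(r))
  })
  out <- dplyr::bind_rows(out)
  out$p_bonf <- pmin(1, out$p * n_comparisons)
  out$included <- out$p_bonf < alpha & out$effect_size >= effect_min
  out[, c("electrode", "p", "p_bonf", "effect_size", "included")]
}
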