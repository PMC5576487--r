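#' HFB recording container
#'
#' Holds one or more electrodes' continuous high-frequency broadband
#' envelope traces in baseline-SD units, on a common analysis-rate grid,
#' with a per-sample validity flag.
#'
#' @param data numeric matrix, samples x electrodes (a vector is treated
#'   as one electrode).
#' @param fs sampling rate, Hz.
#' @param electrodes tibble of electrode metadata with at least an
#'   `electrode` column; `subject` and `roi` are used by aggregation.
#' @param validity logical vector, one flag per sample; invalid samples
#'   are excluded from model fits.
#' @param units character description of the amplitude units.
#' @return an `hfb_recording` object.
#' @export
hfb_recording <- function(data, fs,
                          electrodes = NULL,
                          validity = NULL,
                          units = "baseline-SD") {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(electrodes)) {
    ids <- colnames(data)
    if (is.null(ids)) ids <- sprintf("e%03d", seq_len(ncol(data)))
    electrodes <- tibble::tibble(electrode = ids)
  }
  stopifnot(nrow(electrodes) == ncol(data))
  if (is.null(validity)) validity <- rep(TRUE, nrow(data))
  stopifnot(length(validity) == nrow(data))
  structure(list(data = data, fs = fs, electrodes = electrodes,
                 validity = validity, units = units),
            class = "hfb_recording")
}

#' @export
print.hfb_recording <- function(x, ...) {
  cat(sprintf("<hfb_recording> %d samples x %d electrodes @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$units))
  cat(sprintf("  %.1f s, %.1f%% samples valid\n",
              nrow(x$data) / x$fs, 100 * mean(x$validity)))
  invisible(x)
}

#' Number of samples in a recording
#' @param x an `hfb_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$data)

#' Extract one electrode's trace
#' @param x an `hfb_recording`.
#' @param electrode electrode id or column index.
#' @return numeric vector.
#' @export
electrode_trace <- function(x, electrode = 1L) {
  if (is.character(electrode))
    electrode <- match(electrode, x$electrodes$electrode)
  x$data[, electrode]
}
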