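#' Read and write event tables
#'
#' Event tables are plain tab-separated text with one row per event and
#' the columns `event_id`, `subject`, `block`, `trial`, `condition`,
#' `onset_ms`, `offset_ms`, `magnitude_deg`, `magnitude_px` (extra
#' columns such as `face` and `excluded` round-trip unchanged).
#'
#' @param events event tibble.
#' @param path file path.
#' @return `read_event_table()` returns the tibble;
#'   `write_event_table()` returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write a recording as a binary array with a JSON sidecar
#'
#' The trace matrix is stored column-major as little-endian float64 in
#' `<prefix>.f64`; `<prefix>.json` records the electrode ids, sampling
#' rate, units and dimensions needed to reconstruct it.
#'
#' @param rec an [hfb_recording()].
#' @param prefix output path prefix (without extension).
#' @return the prefix, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  con <- file(paste0(prefix, ".f64"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 8, endian = "little")
  sidecar <- list(electrodes = rec$electrodes,
                  sampling_rate_hz = rec$fs,
                  units = rec$units,
                  n_samples = nrow(rec$data),
                  n_electrodes = ncol(rec$data),
                  validity_runs = which(!rec$validity))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  n <- meta$n_samples * meta$n_electrodes
  con <- file(paste0(prefix, ".f64"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  validity <- rep(TRUE, meta$n_samples)
  bad <- unlist(meta$validity_runs)
  if (length(bad)) validity[bad] <- FALSE
  hfb_recording(matrix(x, meta$n_samples, meta$n_electrodes),
                fs = meta$sampling_rate_hz,
                electrodes = tibble::as_tibble(meta$electrodes),
                validity = validity, units = meta$units)
}

#' Stack deconvolution results into a tidy table
#'
#' @param fits named list of `deconv_result`s, keyed by electrode id.
#' @return tibble with `electrode`, `condition`, `time_ms`, `coef`,
#'   `se`, `p`, `p_fdr`.
#' @export
deconv_table <- function(fits) {
  dplyr::bind_rows(lapply(names(fits), function(e) {
    tr <- fits[[e]]$trace
    tr$electrode <- e
    tr[, c("electrode", "condition", "time_ms", "coef", "se", "p", "p_fdr")]
  }))
}

write_tsv_file <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
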