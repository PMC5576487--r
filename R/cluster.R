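#' Largest strictly-positive cluster of a response trace
#'
#' Scans the maximal runs of strictly positive samples and returns the
#' run maximizing area = (sum of samples) x bin width. Using the single
#' largest positive cluster avoids positive responses being offset by
#' negative ones, unlike averaging the whole trace. A trace with no
#' positive sample yields area 0. Exact area ties are broken toward the
#' earliest run (deterministic).
#'
#' @param trace numeric coefficient trace.
#' @param bin_ms bin width, ms.
#' @param time_ms optional time grid (defaults to `0, bin_ms, ...`).
#' @return list with `start_ms`, `end_ms` (half-open run bounds), `area`
#'   (coefficient x ms) and `idx` (sample indices of the run).
#' @export
largest_positive_cluster <- function(trace, bin_ms = 10, time_ms = NULL) {
  stopifnot(all(is.finite(trace)))
  if (is.null(time_ms)) time_ms <- (seq_along(trace) - 1) * bin_ms
  runs <- rle_runs(trace > 0)
  runs <- runs[runs$value, , drop = FALSE]
  if (nrow(runs) == 0)
    return(list(start_ms = NA_real_, end_ms = NA_real_, area = 0,
                idx = integer(0)))
  areas <- vapply(seq_len(nrow(runs)), function(i)
    sum(trace[runs$start[i]:runs$end[i]]) * bin_ms, numeric(1))
  best <- which.max(areas)   # first maximum: earliest run on ties
  list(start_ms = time_ms[runs$start[best]],
       end_ms = time_ms[runs$end[best]] + bin_ms,
       area = areas[best],
       idx = runs$start[best]:runs$end[best])
}
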