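#' Gamma-shaped response kernel
#'
#' Construct a transient response kernel on the analysis-rate time grid.
#' The kernel is a gamma density rescaled so that its mode equals
#' `peak_ms` and its maximum equals `amplitude`; `width_ms` sets the
#' standard deviation of the underlying gamma (roughly the transient's
#' half-width). Support is `[0, support_ms)`: the kernel vector is exactly
#' zero outside that range, so an FIR window covering the support can
#' recover it without truncation bias.
#'
#' @param amplitude peak amplitude, in baseline-SD units.
#' @param peak_ms latency of the peak relative to the alignment point, ms.
#' @param width_ms dispersion (SD) of the transient, ms.
#' @param support_ms kernel support length, ms; samples at and beyond this
#'   latency are zero.
#' @param fs sampling rate of the analysis grid, Hz.
#' @return numeric vector of length `support_ms / 1000 * fs`, the kernel
#'   sampled at latencies `0, 1/fs, 2/fs, ...` (in seconds), with a
#'   `time_ms` attribute.
#' @examples
#' k <- gamma_kernel(amplitude = 3, peak_ms = 170, width_ms = 60)
#' max(k) # 3 at the sample nearest 170 ms
#' @export
gamma_kernel <- function(amplitude, peak_ms, width_ms, support_ms = 500,
                         fs = 100) {
  stopifnot(peak_ms > 0, width_ms > 0, support_ms > 0, fs > 0)
  n <- round(support_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  # gamma with mode m and sd s: scale u solves u^2 + m*u - s^2 = 0
  u <- (-peak_ms + sqrt(peak_ms^2 + 4 * width_ms^2)) / 2
  shape <- peak_ms / u + 1
  g <- dgamma(t_ms, shape = shape, scale = u)
  peak <- dgamma((shape - 1) * u, shape = shape, scale = u)
  k <- amplitude * g / peak
  attr(k, "time_ms") <- t_ms
  k
}

#' Kernel specification helper
#'
#' @param amplitude peak amplitude in baseline-SD units.
#' @param peak_ms peak latency in ms.
#' @param width_ms dispersion in ms.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(amplitude, peak_ms, width_ms) {
  stopifnot(is.numeric(amplitude), peak_ms > 0, width_ms > 0)
  structure(list(amplitude = amplitude, peak_ms = peak_ms,
                 width_ms = width_ms),
            class = "kernel_spec")
}

realize_kernel <- function(spec, support_ms = 500, fs = 100) {
  gamma_kernel(spec$amplitude, spec$peak_ms, spec$width_ms,
               support_ms = support_ms, fs = fs)
}
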