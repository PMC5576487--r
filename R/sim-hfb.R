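#' Simulate a continuous HFB trace from a schedule
#'
#' The signal model is strict linear superposition: each event adds its
#' condition's kernel at the event's alignment point (the offset for
#' displacements, saccades, blinks and gaps; the onset for stimulus
#' appearances), on top of stationary AR(1) noise in baseline-SD units.
#' The additivity mirrors the assumption under which the FIR GLM
#' deconvolution is exact, so the noise-free trace doubles as an oracle
#' for recovery tests.
#'
#' @param schedule an event tibble from [simulate_event_schedule()].
#' @param kernels named list of numeric kernel vectors (e.g. from
#'   [gamma_kernel()]), one per condition present in `schedule`; saccade
#'   stratum conditions may share a single `saccade` entry.
#' @param ar1 lag-one autocorrelation of the noise.
#' @param innovation_sd innovation SD (default gives unit marginal SD).
#' @param fs sampling rate, Hz.
#' @param duration_ms recording length; defaults to the schedule's.
#' @param seed noise seed; `NULL` leaves the RNG stream untouched.
#' @param noise include the AR(1) noise (set `FALSE` for a noise-free
#'   recording).
#' @return an [hfb_recording()] with one electrode and an extra `clean`
#'   element, the noise-free trace.
#' @export
simulate_hfb <- function(schedule, kernels, ar1 = 0.8,
                         innovation_sd = sqrt(1 - ar1^2),
                         fs = 100, duration_ms = NULL, seed = NULL,
                         noise = TRUE) {
  if (is.null(duration_ms)) duration_ms <- attr(schedule, "duration_ms")
  if (is.null(duration_ms))
    duration_ms <- max(schedule$offset_ms) + 1000
  n <- round(duration_ms / 1000 * fs)
  clean <- numeric(n)
  ev <- schedule[!schedule$excluded %in% TRUE, ]
  for (i in seq_len(nrow(ev))) {
    k <- resolve_kernel(kernels, ev$condition[i])
    if (length(k) > n) stop("kernel longer than the recording", call. = FALSE)
    a <- round(alignment_ms(ev[i, ]) / 1000 * fs) + 1L
    idx <- a + seq_along(k) - 1L
    ok <- idx >= 1L & idx <= n
    clean[idx[ok]] <- clean[idx[ok]] + k[ok]
  }
  x <- clean
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    eps <- as.numeric(arima.sim(model = list(ar = ar1), n = n,
                                sd = innovation_sd))
    x <- clean + eps
  }
  rec <- hfb_recording(x, fs = fs)
  rec$clean <- clean
  rec
}

# alignment point: onset for stimulus conditions, offset otherwise
alignment_ms <- function(events) {
  ifelse(startsWith(events$condition, "stimulus"),
         events$onset_ms, events$offset_ms)
}

resolve_kernel <- function(kernels, condition) {
  k <- kernels[[condition]]
  if (is.null(k) && startsWith(condition, "saccade"))
    k <- kernels[["saccade"]]
  if (is.null(k) && startsWith(condition, "displacement"))
    k <- kernels[["displacement"]]
  if (is.null(k))
    stop("no kernel defined for condition '", condition, "'", call. = FALSE)
  k
}

#' Simulate a full multi-subject cohort with known ground truth
#'
#' Electrodes are spread over subjects round-robin within each ROI. Every
#' electrode of a ROI shares that ROI's suppression factor `s`: its
#' saccade kernel is `(1 - s)` times the displacement kernel and its
#' blink kernel `(1 - s)` times the gap kernel (the generator couples the
#' two suppressions, emulating a shared oculomotor gating pathway).
#' All randomness derives from `config$seed` via fixed sub-streams, so a
#' given configuration is bit-reproducible.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list: `config`, `electrodes` metadata tibble
#'   (`electrode`, `subject`, `roi`, `suppression_factor`, `true_index`),
#'   `schedules` (per subject), `recordings` (per subject, an
#'   [hfb_recording()] of that subject's electrodes), `clean` traces, and
#'   `kernels` (the realized base kernel vectors).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  rois <- names(config$electrodes_per_roi)
  meta <- dplyr::bind_rows(lapply(rois, function(r) {
    m <- config$electrodes_per_roi[[r]]
    if (m == 0) return(NULL)
    tibble::tibble(roi = r,
                   subject = ((seq_len(m) - 1L) %% config$n_subjects) + 1L)
  }))
  if (is.null(meta) || nrow(meta) == 0) {
    meta <- tibble::tibble(electrode = character(), subject = integer(),
                           roi = character(), suppression_factor = numeric(),
                           true_index = numeric())
    return(structure(list(config = config, electrodes = meta,
                          schedules = list(), recordings = list(),
                          kernels = list()),
                     class = "sim_cohort"))
  }
  meta <- meta %>%
    dplyr::arrange(.data$subject, .data$roi) %>%
    dplyr::mutate(electrode = sprintf("e%03d", dplyr::row_number()),
                  suppression_factor =
                    unname(config$suppression_factor[.data$roi]),
                  true_index = implied_suppression_index(.data$suppression_factor)) %>%
    dplyr::select("electrode", "subject", "roi", "suppression_factor",
                  "true_index")

  base <- lapply(config$kernels, realize_kernel, support_ms = 500,
                 fs = config$fs)
  seeds <- substream_seeds(config$seed, config$n_subjects + nrow(meta))
  schedules <- lapply(seq_len(config$n_subjects), function(s) {
    simulate_event_schedule(config, subject = s, seed = seeds[s])
  })
  recordings <- list()
  electrode_kernels <- list()
  for (s in seq_len(config$n_subjects)) {
    el <- meta[meta$subject == s, ]
    if (nrow(el) == 0) next
    traces <- clean <- NULL
    for (j in seq_len(nrow(el))) {
      set.seed(seeds[config$n_subjects +
                       match(el$electrode[j], meta$electrode)])
      f <- 1 - el$suppression_factor[j]
      kern <- base
      # per-electrode retinal-lag jitter, shared by the two movement
      # conditions so their latencies co-vary across electrodes
      if (config$peak_jitter_sd_ms > 0) {
        jit <- rnorm(1, 0, config$peak_jitter_sd_ms)
        dsp <- config$kernels$displacement
        kern$displacement <- realize_kernel(
          kernel_spec(dsp$amplitude, max(60, dsp$peak_ms + jit),
                      dsp$width_ms), fs = config$fs)
        kern$saccade <- kern$displacement
      }
      kern$saccade <- kern$saccade * f
      kern$blink <- base$blink * f
      electrode_kernels[[el$electrode[j]]] <- kern
      rec <- simulate_hfb(schedules[[s]], kern, ar1 = config$ar1,
                          innovation_sd = config$innovation_sd,
                          fs = config$fs, seed = NULL)
      traces <- cbind(traces, rec$data[, 1])
      clean <- cbind(clean, rec$clean)
    }
    colnames(traces) <- colnames(clean) <- el$electrode
    r <- hfb_recording(traces, fs = config$fs, electrodes = el)
    r$clean <- clean
    recordings[[s]] <- r
  }
  structure(list(config = config, electrodes = meta, schedules = schedules,
                 recordings = recordings, kernels = base,
                 electrode_kernels = electrode_kernels),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects, %d electrodes, %d ROIs\n",
              x$config$n_subjects, nrow(x$electrodes),
              length(unique(x$electrodes$roi))))
  invisible(x)
}
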