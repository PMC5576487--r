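# shared miniature fixtures, built in code

tiny_config <- function(seed = 42L, n_blocks = 8, ...) {
  sim_config(n_subjects = 1, electrodes_per_roi = c(V1 = 1),
             n_blocks = n_blocks, fixation_fraction = 0.5,
             peak_jitter_sd_ms = 0, seed = seed, ...)
}

tiny_schedule <- function(seed = 42L, ...) {
  simulate_event_schedule(tiny_config(seed = seed, ...), subject = 1L)
}

tiny_kernels <- function(config = tiny_config()) {
  lapply(config$kernels, realize_kernel, fs = config$fs)
}

# independent enumeration of all permutations of 1..n (test-side oracle,
# distinct from the package's internal enumeration)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}
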