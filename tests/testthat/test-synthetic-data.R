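test_that("schedule geometry follows the block paradigm", {
  cfg <- sim_config(n_subjects = 1, electrodes_per_roi = c(V1 = 1),
                    n_blocks = 12, fixation_fraction = 0.5, seed = 9)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  stim <- sch[startsWith(sch$condition, "stimulus"), ]
  expect_equal(nrow(stim), 12 * 10)  # one onset per trial
  blocks <- attr(sch, "blocks")
  expect_equal(nrow(blocks), 12)
  expect_true(all(blocks$end_ms - blocks$start_ms == 10 * 1000))

  # fixation-block trials carry exactly one displacement at an allowed
  # latency and magnitude
  disp <- sch[startsWith(sch$condition, "displacement"), ]
  fix_blocks <- blocks$block[blocks$type == "fixation"]
  expect_equal(sort(unique(disp$block)), sort(fix_blocks))
  expect_equal(nrow(disp), length(fix_blocks) * 10)
  lat <- disp$onset_ms - blocks$start_ms[disp$block] -
    (disp$trial - 1) * 1000
  expect_true(all(lat %in% c(300, 500, 700)))
  expect_true(all(disp$magnitude_deg %in% c(1.3, 3.7)))

  # saccades only in free-viewing blocks, stratified by magnitude
  sacc <- sch[startsWith(sch$condition, "saccade"), ]
  expect_true(all(blocks$type[sacc$block] == "free"))
  expect_true(all(sacc$offset_ms > sacc$onset_ms))
  in_range <- sacc$magnitude_deg >= 1.3 & sacc$magnitude_deg <= 3.7
  expect_equal(sacc$condition == "saccade_in_range", in_range)
})

test_that("degenerate rates give zero events and bad configs error", {
  sch <- tiny_schedule(seed = 1, saccade_rate_hz = 0, blink_rate_hz = 0,
                       gap_rate_hz = 0)
  expect_equal(sum(startsWith(sch$condition, "saccade")), 0)
  expect_equal(sum(sch$condition == "blink"), 0)
  expect_error(sim_config(trial_ms = -5), "positive")
  expect_error(sim_config(electrodes_per_roi = c(V1 = 1),
                          suppression_factor = c(V1 = 1.5)),
               "\\[0, 1\\]")
  expect_error(sim_config(displacement_latencies_ms = c(200, 500, 700)),
               "300, 500, 700")
  expect_error(sim_config(trials_per_block = 8), "fixed at 10")
})

test_that("schedules and cohorts are seed-deterministic", {
  expect_identical(tiny_schedule(seed = 7), tiny_schedule(seed = 7))
  cfg <- sim_config(n_subjects = 2, electrodes_per_roi = c(V1 = 1, V4 = 1),
                    n_blocks = 4, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$recordings[[1]]$data, c2$recordings[[1]]$data)
  expect_identical(c1$schedules, c2$schedules)
})

test_that("noise-free traces are the exact superposition of kernels", {
  cfg <- tiny_config()
  kern <- tiny_kernels(cfg)
  # single event: trace equals the kernel at its alignment point
  ev <- tibble::tibble(event_id = 1L, subject = 1L, block = 1L, trial = 1L,
                       condition = "displacement_small", onset_ms = 2000,
                       offset_ms = 2000, magnitude_deg = 1.3,
                       magnitude_px = 50, face = FALSE, excluded = FALSE)
  rec <- simulate_hfb(ev, kern, fs = 100, duration_ms = 5000, noise = FALSE)
  a <- round(2000 / 1000 * 100) + 1
  expect_equal(rec$data[a:(a + 49), 1], as.numeric(kern$displacement))
  expect_true(all(rec$data[-(a:(a + 49)), 1] == 0))

  # two overlapping events: exact sum of shifted kernels
  ev2 <- dplyr::bind_rows(ev, dplyr::mutate(ev, onset_ms = 2130,
                                            offset_ms = 2130))
  rec2 <- simulate_hfb(ev2, kern, fs = 100, duration_ms = 5000,
                       noise = FALSE)
  manual <- numeric(500)
  manual[a + 0:49] <- manual[a + 0:49] + kern$displacement
  manual[(a + 13) + 0:49] <- manual[(a + 13) + 0:49] + kern$displacement
  expect_equal(rec2$data[, 1], manual)

  # full schedule: trace equals convolution of event trains with kernels
  sch <- tiny_schedule()
  rec3 <- simulate_hfb(sch, kern, noise = FALSE)
  n <- nrow(rec3$data)
  conv <- numeric(n)
  for (i in seq_len(nrow(sch))) {
    k <- saccsupp:::resolve_kernel(kern, sch$condition[i])
    al <- if (startsWith(sch$condition[i], "stimulus")) sch$onset_ms[i]
          else sch$offset_ms[i]
    a <- round(al / 10) + 1
    idx <- a + seq_along(k) - 1
    ok <- idx <= n
    conv[idx[ok]] <- conv[idx[ok]] + k[ok]
  }
  expect_equal(rec3$data[, 1], conv)
  expect_error(simulate_hfb(ev, list(displacement = numeric(1e6)),
                            fs = 100, duration_ms = 5000),
               "longer than the recording")
})

test_that("simulated AR(1) noise has the configured autocorrelation", {
  sch <- tiny_schedule(saccade_rate_hz = 0, blink_rate_hz = 0,
                       gap_rate_hz = 0)
  sch <- sch[0, ]  # noise-only recording
  rec <- simulate_hfb(sch, list(), ar1 = 0.8, fs = 100,
                      duration_ms = 1.2e6, seed = 4)
  x <- rec$data[, 1]
  phi_hat <- sum(x[-1] * x[-length(x)]) / sum(x^2)  # Yule-Walker lag 1
  expect_lt(abs(phi_hat - 0.8), 0.05)
  expect_lt(abs(sd(x) - 1), 0.05)  # baseline-SD units by construction
})

test_that("realized event counts match their Poisson expectations", {
  cfg <- tiny_config(seed = 5, n_blocks = 40, blink_rate_hz = 0,
                     gap_rate_hz = 0)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  n_sacc <- sum(startsWith(sch$condition, "saccade"))
  free_s <- sum(attr(sch, "blocks")$type == "free") * 10
  expected <- cfg$saccade_rate_hz * free_s
  # overlap pruning removes a few percent; allow 3 SD below plus margin
  expect_gt(n_sacc, expected - 4 * sqrt(expected))
  expect_lt(n_sacc, expected + 3 * sqrt(expected))
})

test_that("simulated gaze realizes magnitudes, blinks and constancy", {
  cfg <- tiny_config()
  # single constructed saccade of 2 degrees
  ev <- tibble::tibble(event_id = 1:2, subject = 1L, block = 1L,
                       trial = 1L,
                       condition = c("saccade_in_range", "blink"),
                       onset_ms = c(1000, 3000),
                       offset_ms = c(1030, 3200),
                       magnitude_deg = c(2.0, NA), magnitude_px = NA,
                       face = FALSE, excluded = FALSE)
  gz <- simulate_gaze(ev, duration_ms = 5000, seed = 8)
  pre <- gz[gz$time_ms < 990, ]
  post <- gz[gz$time_ms > 1040 & gz$time_ms < 2990, ]
  d <- sqrt((mean(post$x_deg) - mean(pre$x_deg))^2 +
              (mean(post$y_deg) - mean(pre$y_deg))^2)
  expect_equal(d, 2.0, tolerance = 1e-6)
  expect_true(all(!gz$valid[gz$time_ms >= 3002 & gz$time_ms <= 3198]))
  expect_true(all(gz$valid[gz$time_ms < 3000]))

  # no events: constant gaze
  gz0 <- simulate_gaze(ev[0, ], duration_ms = 1000)
  expect_equal(var(gz0$x_deg), 0)
  # overlapping saccades rejected
  bad <- dplyr::mutate(ev[c(1, 1), ],
                       onset_ms = c(1000, 1010), offset_ms = c(1030, 1040))
  expect_error(simulate_gaze(bad, duration_ms = 5000), "overlapping")
})
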