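test_that("design matrix has the promised indicator structure", {
  spec <- design_spec(conditions = list(
    a = list(window = c(0, 50), align = "onset"),
    b = list(window = c(0, 50), align = "onset")))
  ev <- tibble::tibble(event_id = 1:3, subject = 1, block = 1, trial = 1,
                       condition = c("a", "b", "a"),
                       onset_ms = c(100, 400, 700),
                       offset_ms = c(100, 400, 700),
                       magnitude_deg = NA, magnitude_px = NA,
                       face = NA, excluded = FALSE)
  D <- build_design_matrix(ev, spec, n_samples = 100, fs = 100)
  # one event, K bins -> K columns with exactly one 1 (condition b)
  bcols <- D$col_map$col[D$col_map$condition == "b"]
  expect_equal(unname(Matrix::colSums(D$X[, bcols])), rep(1, 5))
  expect_equal(unname(Matrix::colSums(D$X != 0)[bcols]), rep(1, 5))
  # disjoint conditions never share rows
  acols <- D$col_map$col[D$col_map$condition == "a"]
  overlap <- Matrix::rowSums(D$X[, acols]) *
    Matrix::rowSums(D$X[, bcols])
  expect_true(all(overlap == 0))
  # excluded events contribute nothing
  ev2 <- dplyr::mutate(ev, excluded = c(FALSE, TRUE, FALSE))
  D2 <- build_design_matrix(ev2, spec, 100, 100)
  expect_false("b" %in% D2$col_map$condition)
  # windows past the recording edge truncate with a warning
  expect_warning(build_design_matrix(ev, spec, n_samples = 72, fs = 100),
                 "truncated")
})

test_that("overlapping same-condition events sum across, not within, columns", {
  spec <- design_spec(conditions = list(
    a = list(window = c(-300, 500), align = "offset")))
  ev <- tibble::tibble(event_id = 1:2, subject = 1, block = 1, trial = 1,
                       condition = "a", onset_ms = c(1000, 1100),
                       offset_ms = c(1000, 1100), magnitude_deg = NA,
                       magnitude_px = NA, face = NA, excluded = FALSE)
  D <- build_design_matrix(ev, spec, n_samples = 300, fs = 100)
  expect_equal(max(D$X), 1)  # never two events in one (sample, column)
  expect_equal(unname(Matrix::colSums(D$X)), rep(2, 80))
  # rows where the two 800-ms windows overlap carry two predictors
  expect_equal(max(Matrix::rowSums(D$X)), 2)
})

test_that("FIR GLM solves the normal equations (dense oracle, 200 samples)", {
  # small instance with heavy overlap, oracle built independently
  spec <- design_spec(conditions = list(
    a = list(window = c(0, 100), align = "onset"),
    b = list(window = c(0, 100), align = "onset")))
  ev <- tibble::tibble(event_id = 1:5, subject = 1, block = 1, trial = 1,
                       condition = c("a", "b", "a", "b", "a"),
                       onset_ms = c(100, 150, 400, 430, 460),
                       offset_ms = onset_ms, magnitude_deg = NA,
                       magnitude_px = NA, face = NA, excluded = FALSE)
  n <- 200
  set.seed(21)
  y <- rnorm(n)
  D <- build_design_matrix(ev, spec, n_samples = n, fs = 100)
  fit <- fit_fir_glm(y, D)
  # oracle: dense design assembled by explicit loops
  Xd <- matrix(0, n, 20)
  col <- 0
  for (cn in c("a", "b")) {
    for (lag in 0:9) {
      col <- col + 1
      for (i in which(ev$condition == cn)) {
        r <- round(ev$onset_ms[i] / 10) + 1 + lag
        if (r <= n) Xd[r, col] <- Xd[r, col] + 1
      }
    }
  }
  Xd <- cbind(1, Xd)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(fit$trace$coef, beta[-1], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10,
               ignore_attr = TRUE)
  # standard errors match the dense computation
  res <- y - Xd %*% beta
  s2 <- sum(res^2) / (n - ncol(Xd))
  se <- sqrt(s2 * diag(solve(t(Xd) %*% Xd)))
  expect_equal(fit$trace$se, se[-1], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("noiseless overlapping kernels are recovered exactly where
           naive averaging is biased", {
  cfg <- tiny_config(seed = 31)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  kern <- tiny_kernels(cfg)
  rec <- simulate_hfb(sch, kern, noise = FALSE)
  D <- suppressWarnings(
    build_design_matrix(sch, design_spec(), nrow(rec$data), fs = 100))
  fit <- fit_fir_glm(rec$data[, 1], D)
  tr <- get_trace(fit, "displacement_small")
  expect_lt(max(abs(tr$coef[tr$time_ms >= 0] - kern$displacement)), 1e-8)
  expect_lt(max(abs(tr$coef[tr$time_ms < 0])), 1e-8)
  naive <- event_locked_average(rec$data[, 1], sch, "displacement_small",
                                window = c(0, 500), fs = 100)
  expect_gt(max(abs(naive$mean - kern$displacement)), 0.2)
})

test_that("orthogonal designs reduce to event-locked averages and scale
           equivariantly", {
  spec <- design_spec(conditions = list(
    a = list(window = c(0, 300), align = "onset")))
  ev <- tibble::tibble(event_id = 1:6, subject = 1, block = 1, trial = 1,
                       condition = "a", onset_ms = seq(500, 8000, by = 1500),
                       offset_ms = onset_ms, magnitude_deg = NA,
                       magnitude_px = NA, face = NA, excluded = FALSE)
  n <- 1000
  set.seed(5)
  y <- rnorm(n)
  D <- build_design_matrix(ev, spec, n, fs = 100)
  fit <- fit_fir_glm(y, D)
  ela <- event_locked_average(y, ev, "a", window = c(0, 300), fs = 100)
  expect_equal(fit$trace$coef, ela$mean - fit$intercept,
               tolerance = 1e-10)
  fit3 <- fit_fir_glm(3 * y, D)
  expect_equal(fit3$trace$coef, 3 * fit$trace$coef, tolerance = 1e-10)
})

test_that("OLS confidence intervals cover the true kernel under AR(1) noise", {
  cfg <- tiny_config(seed = 8, n_blocks = 6)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  kern <- tiny_kernels(cfg)
  spec <- design_spec(pool_displacements = TRUE)
  D <- suppressWarnings(
    build_design_matrix(sch, spec, round(attr(sch, "duration_ms") / 10),
                        fs = 100))
  clean <- simulate_hfb(sch, kern, noise = FALSE)$data[, 1]
  lag_sel <- D$col_map$condition == "displacement"
  truth <- numeric(sum(lag_sel))
  truth[D$col_map$lag_ms[lag_sel] >= 0] <- kern$displacement
  set.seed(77)
  n_sim <- 300
  covered <- matrix(NA, n_sim, sum(lag_sel))
  for (i in seq_len(n_sim)) {
    y <- clean + as.numeric(arima.sim(list(ar = 0.8), length(clean),
                                      sd = sqrt(1 - 0.8^2)))
    fit <- fit_fir_glm(y, D)
    tr <- get_trace(fit, "displacement")
    covered[i, ] <- abs(tr$coef - truth) <= 1.96 * tr$se
  }
  cov_rate <- colMeans(covered)
  expect_gt(mean(cov_rate), 0.90)
  expect_lt(mean(cov_rate), 0.98)
})

test_that("cross-validated estimates behave: exactness, shrinkage, null", {
  cfg <- tiny_config(seed = 13)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  kern <- tiny_kernels(cfg)
  spec <- design_spec(pool_displacements = TRUE)
  n <- round(attr(sch, "duration_ms") / 10)
  D <- build_design_matrix(sch, spec, n, fs = 100)
  blocks <- attr(sch, "blocks")
  # noiseless: CV estimate equals the full fit
  clean <- simulate_hfb(sch, kern, noise = FALSE)$data[, 1]
  cv <- crossvalidated_estimates(clean, D, blocks, n_folds = 4)
  fit <- fit_fir_glm(clean, D)
  j <- merge(cv$trace, fit$trace, by = c("condition", "time_ms"))
  expect_lt(max(abs(j$coef.x - j$coef.y)), 1e-8)
  # null condition: CV scalar centered on zero across noise draws
  kern0 <- kern
  kern0$saccade <- kern$saccade * 0
  clean0 <- simulate_hfb(sch, kern0, noise = FALSE)$data[, 1]
  sc <- vapply(1:20, function(i) {
    y <- clean0 + as.numeric(arima.sim(list(ar = 0.8), n,
                                       sd = sqrt(1 - 0.64)))
    cvi <- crossvalidated_estimates(y, D, blocks, n_folds = 4)
    scalar_response(cvi$trace, "saccade_in_range")
  }, numeric(1))
  expect_lt(abs(mean(sc)), 2 * sd(sc) / sqrt(length(sc)) + 0.05)
})

test_that("CV estimate variance shrinks as events per fold grow", {
  vars <- vapply(c(4, 8, 16), function(nb) {
    cfg <- tiny_config(seed = 40 + nb, n_blocks = nb)
    sch <- simulate_event_schedule(cfg, subject = 1L)
    kern <- tiny_kernels(cfg)
    spec <- design_spec(pool_displacements = TRUE)
    n <- round(attr(sch, "duration_ms") / 10)
    D <- build_design_matrix(sch, spec, n, fs = 100)
    blocks <- attr(sch, "blocks")
    clean <- simulate_hfb(sch, kern, noise = FALSE)$data[, 1]
    set.seed(nb)
    sc <- vapply(1:12, function(i) {
      y <- clean + as.numeric(arima.sim(list(ar = 0.8), n,
                                        sd = sqrt(1 - 0.64)))
      scalar_response(crossvalidated_estimates(y, D, blocks,
                                               n_folds = 4)$trace,
                      "displacement")
    }, numeric(1))
    var(sc)
  }, numeric(1))
  expect_true(vars[3] < vars[1])  # monotone trend over a 4x size range
})

test_that("scalar responses integrate the trace over the window", {
  tr <- tibble::tibble(condition = "a", time_ms = seq(0, 490, by = 10),
                       coef = 2.5)
  expect_equal(scalar_response(tr, "a"), 2.5)
  k <- gamma_kernel(3, 170, 60)
  trk <- tibble::tibble(condition = "a", time_ms = attr(k, "time_ms"),
                        coef = as.numeric(k))
  expect_equal(scalar_response(trk, "a"), mean(k))
  expect_error(scalar_response(trk, "a", window = c(600, 700)), "empty")
})

test_that("onset- and offset-aligned estimates agree for short saccades", {
  cfg <- tiny_config(seed = 55)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  kern <- tiny_kernels(cfg)
  rec <- simulate_hfb(sch, kern, seed = 19)
  n <- nrow(rec$data)
  spec_off <- design_spec(pool_displacements = TRUE)
  spec_on <- spec_off
  for (cn in c("displacement", "saccade_in_range", "saccade_below",
               "saccade_above"))
    spec_on$conditions[[cn]]$align <- "onset"
  f_off <- fit_fir_glm(rec$data[, 1],
                       build_design_matrix(sch, spec_off, n, 100))
  f_on <- fit_fir_glm(rec$data[, 1],
                      build_design_matrix(sch, spec_on, n, 100))
  a <- get_trace(f_off, "saccade_in_range")
  b <- get_trace(f_on, "saccade_in_range")
  sel <- a$time_ms >= 0
  expect_gt(cor(a$coef[sel], b$coef[sel]), 0.9)
})

test_that("rank-deficient designs fall back to minimum norm with flags", {
  spec <- design_spec(conditions = list(
    a = list(window = c(0, 100), align = "onset"),
    b = list(window = c(0, 100), align = "onset")))
  # identical event times for both conditions: perfectly collinear
  ev <- tibble::tibble(event_id = 1:4, subject = 1, block = 1, trial = 1,
                       condition = c("a", "b", "a", "b"),
                       onset_ms = c(100, 100, 500, 500),
                       offset_ms = onset_ms, magnitude_deg = NA,
                       magnitude_px = NA, face = NA, excluded = FALSE)
  set.seed(9)
  D <- build_design_matrix(ev, spec, 200, fs = 100)
  expect_warning(fit <- fit_fir_glm(rnorm(200), D), "minimum-norm")
  expect_true(fit$rank_deficient)
  expect_true(any(!fit$trace$estimable))
})
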