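test_that("largest positive cluster follows its definition", {
  # runs are {2,3} (area 5) and {1} (area 1)
  cl <- largest_positive_cluster(c(-1, 2, 3, -0.5, 1), bin_ms = 1)
  expect_equal(cl$area, 5)
  expect_equal(cl$idx, 2:3)
  expect_equal(cl$start_ms, 1)
  expect_equal(cl$end_ms, 3)
  # no positive sample: area 0
  expect_equal(largest_positive_cluster(c(-2, -1, 0))$area, 0)
  # exact area tie: earliest run wins
  tie <- largest_positive_cluster(c(1, 1, -1, 2), bin_ms = 1)
  expect_equal(tie$idx, 1:2)
  # area invariant to negatives outside the selected run
  a1 <- largest_positive_cluster(c(-1, 2, 3, -0.5, 1), bin_ms = 1)$area
  a2 <- largest_positive_cluster(c(-9, 2, 3, -7, 1), bin_ms = 1)$area
  expect_equal(a1, a2)
  # fast path used inside the permutation loop agrees
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(50)
    expect_equal(saccsupp:::cluster_area_max(x, 10),
                 largest_positive_cluster(x, 10)$area)
  }
})

test_that("label-shuffle contrast: fast path equals the literal full refit", {
  cfg <- tiny_config(seed = 11, n_blocks = 6)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  kern <- tiny_kernels(cfg)
  rec <- simulate_hfb(sch, kern, seed = 5)
  spec <- design_spec()
  y <- rec$data[, 1]
  n <- length(y)
  eng <- saccsupp:::contrast_engine(y, sch, spec, n, 100, NULL,
                                    "displacement", "saccade_in_range")
  set.seed(1)
  for (i in 1:3) {
    g <- sample(eng$g_obs)
    fast <- saccsupp:::contrast_fit(eng, g)
    slow <- contrast_stat_full_refit(y, sch, spec, n, 100, assignment = g)
    expect_equal(fast$beta_pos, slow$beta_pos, tolerance = 1e-10)
    expect_equal(fast$beta_neg, slow$beta_neg, tolerance = 1e-10)
    expect_equal(fast$stat, slow$stat, tolerance = 1e-8)
  }
  # swapping all labels negates the statistic
  fwd <- saccsupp:::contrast_fit(eng, eng$g_obs)
  rev <- saccsupp:::contrast_fit(eng, 3L - eng$g_obs)
  expect_equal(fwd$stat, -rev$stat, tolerance = 1e-8)
})

test_that("permutation p-values are valid and consistent", {
  cfg <- tiny_config(seed = 19, n_blocks = 6)
  sch <- simulate_event_schedule(cfg, subject = 1L)
  kern <- tiny_kernels(cfg)
  rec <- simulate_hfb(sch, kern, seed = 2)
  pt <- cluster_area_perm_test(rec$data[, 1], sch, design_spec(),
                               fs = 100, n_perm = 99, seed = 7)
  expect_gte(pt$p_pos_gt_neg, 1 / 100)
  expect_gte(pt$p_neg_gt_pos, 1 / 100)
  # the two one-sided p-values come from the same null distribution
  expect_gte(pt$p_pos_gt_neg + pt$p_neg_gt_pos, 1)
  expect_equal(length(pt$null_stats), 99)
  # too few events in a group: skipped with a warning
  few <- sch[!startsWith(sch$condition, "displacement") |
               seq_len(nrow(sch)) %in%
               head(which(startsWith(sch$condition, "displacement")), 1), ]
  expect_warning(
    out <- cluster_area_perm_test(rec$data[, 1], few, design_spec(),
                                  n_samples = nrow(rec$data), fs = 100,
                                  n_perm = 10),
    "fewer than 2")
  expect_null(out)
})

test_that("ROI independence randomization matches its oracles", {
  # perfectly balanced table: chi-square 0, p near 1
  roi <- rep(c("A", "B"), each = 10)
  sig <- rep(c(TRUE, FALSE), 10)
  r0 <- roi_independence_test(roi, sig, n_rand = 200, seed = 1)
  expect_equal(r0$chisq, 0, tolerance = 1e-12)
  expect_gt(r0$p, 0.95)
  # perfect association in a balanced 2x2: chi-square = n = 20
  r1 <- roi_independence_test(roi, roi == "A", n_rand = 200, seed = 1)
  expect_equal(r1$chisq, 20, tolerance = 1e-12)
  # exact enumeration oracle, 6 electrodes in 2 ROIs
  roi6 <- c("A", "A", "A", "B", "B", "B")
  sig6 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  obs <- suppressWarnings(
    chisq.test(table(roi6, sig6), correct = FALSE)$statistic)
  stats_all <- apply(utils::combn(6, 3), 2, function(ia) {
    r <- rep("B", 6); r[ia] <- "A"
    suppressWarnings(chisq.test(table(r, sig6), correct = FALSE)$statistic)
  })
  p_exact <- mean(stats_all >= obs - 1e-12)
  n_rand <- 4000
  r2 <- roi_independence_test(roi6, sig6, n_rand = n_rand, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / n_rand)
  expect_lt(abs(r2$p - p_exact), 3 * se + 1 / (n_rand + 1))
})

test_that("peak latency divides by SE and gates on significance", {
  mk <- function(coef, se, p_fdr) {
    structure(list(trace = tibble::tibble(
      condition = "c", time_ms = seq(0, by = 10,
                                     length.out = length(coef)),
      coef = coef, se = se, p = p_fdr, p_fdr = p_fdr,
      estimable = TRUE)), class = "deconv_result")
  }
  bump <- exp(-(seq(0, 490, by = 10) - 170)^2 / (2 * 50^2))
  r <- mk(bump, rep(1, 50), rep(0.001, 50))
  expect_equal(peak_latency(r, "c"), 170)
  # two bumps; the earlier has half the SE, so it wins after division
  two <- 0.9 * exp(-(seq(0, 490, by = 10) - 100)^2 / (2 * 30^2)) +
    1.0 * exp(-(seq(0, 490, by = 10) - 350)^2 / (2 * 30^2))
  se2 <- ifelse(seq(0, 490, by = 10) < 220, 0.5, 1)
  r2 <- mk(two, se2, rep(0.001, 50))
  expect_equal(peak_latency(r2, "c"), 100)
  # flat trace or no significant positive bin: undefined
  expect_true(is.na(peak_latency(mk(rep(0, 50), rep(1, 50),
                                    rep(0.001, 50)), "c")))
  expect_true(is.na(peak_latency(mk(bump, rep(1, 50), rep(0.5, 50)), "c")))
})

test_that("latency comparison handles identical and generic inputs", {
  ident <- latency_comparison(c(100, 150, 200, 250), c(100, 150, 200, 250))
  expect_equal(ident$r, 1)
  expect_equal(ident$t, 0)
  expect_error(latency_comparison(c(100, NA, NA, 120), c(1, 2, NA, 4)),
               "at least 3")
  set.seed(8)
  shift <- latency_comparison(c(100, 150, 200, 250, 300) + rnorm(5, 0, 1),
                              c(100, 150, 200, 250, 300) - 20)
  expect_gt(shift$r, 0.99)
  expect_gt(shift$t, 2)
})

test_that("suppression indices follow the definition and its edge cases", {
  sc <- tibble::tibble(
    electrode = sprintf("e%d", 1:4), roi = c("X", "X", "Y", "Y"),
    gap = c(2, 1, 1, 1), blink = c(1, 1, 0.5, 1),
    displacement = c(2, 1, 1, 1), saccade = c(1, 0, -0.5, -1))
  si <- suppressMessages(suppression_indices(sc))
  el <- si$electrodes
  expect_equal(el$saccade_index[1], 1 / 3)       # (2-1)/(2+1)
  expect_equal(el$saccade_index[2], 1)           # full suppression
  expect_equal(el$saccade_index[3], 3)           # negative response, > 1
  expect_true(is.na(el$saccade_index[4]))        # zero denominator
  # antisymmetry: swapping the two scalars negates the index
  sw <- suppression_indices(dplyr::mutate(sc[1:3, ],
                                          tmp = displacement,
                                          displacement = saccade,
                                          saccade = tmp))
  expect_equal(sw$electrodes$saccade_index, -el$saccade_index[1:3])
  # ROI means skip undefined entries
  expect_equal(si$roi$saccade_mean[si$roi$roi == "Y"], 3)
})

test_that("Dice coefficient and its permutation test behave", {
  u <- 1:20
  expect_equal(dice_overlap_test(1:5, 1:5, u, n_perm = 10)$dice, 1)
  expect_equal(dice_overlap_test(1:5, 6:10, u, n_perm = 10)$dice, 0)
  expect_equal(dice_overlap_test(c(1, 2, 3), c(2, 3, 4), u,
                                 n_perm = 10)$dice, 2 * 2 / 6)
  # symmetry and monotonicity in the intersection size
  d1 <- dice_overlap_test(1:4, 3:7, u, n_perm = 10)$dice
  d2 <- dice_overlap_test(3:7, 1:4, u, n_perm = 10)$dice
  expect_equal(d1, d2)
  d3 <- dice_overlap_test(1:4, 2:6, u, n_perm = 10)$dice
  expect_gt(d3, d1)  # |A n B| grows, sizes fixed
  expect_error(dice_overlap_test(integer(0), integer(0), u, n_perm = 10),
               "undefined")
  # strong overlap is detected as above chance
  set.seed(2)
  d <- dice_overlap_test(1:6, 2:7, u, n_perm = 2000, seed = 3)
  expect_lt(d$p, 0.01)
  expect_gte(d$p, 1 / 2001)
})

test_that("outlier-removal correlation test: observed statistic and nulls", {
  # six collinear points plus one off-line point
  x <- c(1:6, 10)
  y <- c(2 * (1:6) + 1, 0)
  r <- outlier_robust_correlation_test(x, y, designated_outlier = 7,
                                       n_shuffle = 200, seed = 1)
  expect_equal(r$observed_r, 1, tolerance = 1e-12)
  expect_true(r$exhaustive == FALSE || factorial(7) <= 200)
  expect_gte(r$p, 0)
  # n = 5 with ample budget: exhaustive enumeration kicks in
  set.seed(4)
  r5 <- outlier_robust_correlation_test(rnorm(5), rnorm(5), 1,
                                        n_shuffle = 200)
  expect_true(r5$exhaustive)
  expect_equal(length(r5$null_stats), 120)
  expect_error(outlier_robust_correlation_test(c(1, 1, 1, 1, 2),
                                               c(1, 2, 3, 4, 5), 5,
                                               n_shuffle = 10),
               "constant")
})
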