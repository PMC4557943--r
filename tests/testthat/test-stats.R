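test_that("uncorrected 2x2 chi-square matches hand values and symmetries", {
  res <- chi2_2x2(29, 10, 79, 144)
  expect_equal(round(res$statistic, 1), 20.8)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  expect_equal(round(chi2_2x2(3, 8, 6, 1)$statistic, 2), 5.84)
  expect_equal(chi2_2x2(10, 10, 10, 10)$statistic, 0)

  # invariance under transposition and row/column swaps
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(sample(1:50, 4, replace = TRUE), 2)
    s <- chi2_2x2(m)$statistic
    expect_equal(chi2_2x2(t(m))$statistic, s)
    expect_equal(chi2_2x2(m[2:1, ])$statistic, s)
    expect_equal(chi2_2x2(m[, 2:1])$statistic, s)
  }
  expect_error(chi2_2x2(0, 0, 5, 5), "margins")
})

test_that("goodness-of-fit chi-square normalises weights to the observed total", {
  expect_equal(chi2_gof(c(25, 25, 25, 25))$statistic, 0)
  expect_equal(chi2_gof(c(66, 67, 62, 65), c(178, 179, 175, 173))$statistic,
               0.139, tolerance = 1e-3)
  expect_equal(chi2_gof(c(10, 0), c(1, 1))$statistic, 10)
  expect_error(chi2_gof(c(1, 2), c(1, 0)), "positive")
  expect_error(chi2_gof(c(1, 2, 3), c(1, 2)), "length")
})

test_that("Mann-Whitney U uses the 0.5-per-tie convention and reports the minimum", {
  drv <- mann_whitney_u(c(rep(1, 6), 0), rep(1, 7))
  expect_equal(drv$u, 21)

  sep <- mann_whitney_u(1:5, 11:15)
  expect_equal(sep$u, 0)

  # brute-force pair-enumeration oracle, with ties
  set.seed(6)
  for (i in 1:30) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 7, replace = TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$u1, u1_brute(x, y))
    expect_equal(got$u1 + got$u2, length(x) * length(y)) # U1 + U2 = n1 n2
    expect_equal(got$u, min(got$u1, got$u2))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("two-sample t covers pooled and Welch variants", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(same$statistic, 0)

  # hand computation: means 0.5 vs 10.5, both sd 1/sqrt(2), pooled SE
  # sqrt(0.5) * sqrt(1/2 + 1/2) = 0.7071 -> t = -10 / 0.7071
  hand <- two_sample_t(c(0, 1), c(10, 11), "pooled")
  expect_equal(hand$statistic, -10 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(hand$df, 2)

  # equal variances and sizes: Welch df equals pooled df
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)
  expect_equal(two_sample_t(x, y, "welch")$df, two_sample_t(x, y, "pooled")$df)

  # otherwise Welch df <= pooled df
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(4:10, 1)); b <- rnorm(sample(4:10, 1), sd = runif(1, 0.2, 3))
    expect_lte(two_sample_t(a, b, "welch")$df, two_sample_t(a, b, "pooled")$df + 1e-9)
  }
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("pearson correlation matches hand computation and affine invariance", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  set.seed(8)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- pearson_r(a, b)$r
  expect_equal(pearson_r(3 * a + 2, b)$r, r0)
  expect_true(abs(r0) <= 1)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("log-RT regression recovers exact structure on noiseless data", {
  df <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 20),
    occlusion_time = rep(seq(0, 1.9, by = 0.1), 2),
    log_rt = 0.5 + 0.3 * rep(seq(0, 1.9, by = 0.1), 2) + rep(c(0, 0.4), each = 20)
  )
  fit <- ols_logrt(df)
  expect_equal(fit$occ_slope, 0.3, tolerance = 1e-10)
  g <- suppressWarnings(glance(fit)) # noiseless fit is intentionally perfect
  expect_equal(g$adj_r_squared, 1, tolerance = 1e-10)
  expect_lte(g$adj_r_squared, g$r_squared + 1e-12)
  td <- suppressWarnings(tidy(fit))
  expect_true("participant_idb" %in% td$term)
  expect_equal(unname(td$estimate[td$term == "participant_idb"]), 0.4, tolerance = 1e-10)

  # degenerate design: constant occlusion is unidentifiable
  flat <- dplyr::mutate(df, occlusion_time = 1)
  expect_error(ols_logrt(flat), "aliased|identifiable")
})

test_that("adjusted R-squared never exceeds R-squared on noisy fits", {
  set.seed(9)
  df <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = 30),
    occlusion_time = runif(90, 0, 2)
  )
  df$log_rt <- 0.2 + 0.3 * df$occlusion_time + rnorm(90, 0, 0.4)
  g <- glance(ols_logrt(df))
  expect_lt(g$adj_r_squared, g$r_squared)
})

test_that("untimely summary builds the occlusion-by-timeliness table", {
  # scripted table reproducing the printed counts: 39 untimely (29 occluded),
  # 223 timely (79 occluded)
  tab <- tibble::tibble(
    event_id = as.character(1:262),
    participant_id = "p",
    drive_type = rep(c("city", "highway"), length.out = 262),
    ecc_class = rep(c("small", "large"), length.out = 262),
    detected = TRUE,
    timely = rep(c(FALSE, TRUE), c(39, 223)),
    occlusion_time = c(rep(c(1, 0), c(29, 10)), rep(c(1, 0), c(79, 144))),
    reaction_time = 1,
    gaze_usable = TRUE
  )
  res <- untimely_summary(tab)
  expect_equal(unname(res$contingency["untimely", "occluded"]), 29)
  expect_equal(unname(res$contingency["timely", "occluded"]), 79)
  expect_equal(round(res$test$statistic, 1), 20.8)
  expect_equal(sum(res$by_stratum$untimely), 39)

  all_timely <- dplyr::mutate(tab, timely = TRUE)
  res2 <- untimely_summary(all_timely)
  expect_true(all(res2$by_stratum$prop_untimely == 0))
})

test_that("median summary gives per-stratum medians with bootstrap intervals", {
  tab <- tibble::tibble(
    reaction_time = c(1, 2, 3, 4, 5),
    group = "one"
  )
  m <- median_summary(tab, by = "group", B = 200, seed = 3)
  expect_equal(m$median, 3)
  expect_lte(m$ci_low, m$median)
  expect_gte(m$ci_high, m$median)

  single <- median_summary(tibble::tibble(reaction_time = 2.5), B = 50, seed = 1)
  expect_equal(single$median, 2.5)
  expect_equal(single$ci_low, single$ci_high)
})

test_that("bootstrap median interval attains nominal-like coverage on lognormal data", {
  # frozen simulation: percentile bootstrap CI for the median on lognormal
  # samples; coverage of the true median should be near nominal
  true_med <- exp(0.7)
  set.seed(123)
  seeds <- sample.int(1e6, 100)
  covered <- vapply(seq_along(seeds), function(i) {
    set.seed(seeds[i])
    v <- exp(rnorm(60, 0.7, 0.5))
    m <- median_summary(tibble::tibble(reaction_time = v), B = 300, seed = seeds[i])
    m$ci_low <= true_med && true_med <= m$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})
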