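test_that("repeated-median fit matches examples and the loop oracle", {
  f <- repeated_median_fit(c(0, 1, 2), c(0, 1, 2), n_boot = 0)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)

  # gross outlier resisted
  f2 <- repeated_median_fit(c(0, 1, 2, 3), c(0, 1, 2, 100), n_boot = 0)
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 0)

  # sign equivariance
  set.seed(71)
  x <- runif(12); y <- 2 * x + rnorm(12, 0, 0.1)
  fa <- repeated_median_fit(x, y, n_boot = 0)
  fb <- repeated_median_fit(x, -y, n_boot = 0)
  expect_equal(fb$slope, -fa$slope)
  expect_equal(fb$r2, fa$r2)

  # exhaustive-loop oracle on random instances
  set.seed(72)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    f <- repeated_median_fit(x, y, n_boot = 0)
    or <- oracle_repeated_median(x, y)
    expect_equal(f$slope, unname(or["slope"]))
    expect_equal(f$intercept, unname(or["intercept"]))
  }
})

test_that("repeated median survives 30% gross outliers", {
  set.seed(73)
  for (rep in 1:5) {
    n <- 20
    x <- runif(n, 0, 10)
    y <- 0.8 * x + 2
    bad <- sample(n, 6)
    y[bad] <- y[bad] + runif(6, 20, 80)
    f <- repeated_median_fit(x, y, n_boot = 0)
    expect_lt(abs(f$slope - 0.8), 0.05)
  }
})

test_that("bootstrap uncertainty is seeded and sane", {
  set.seed(74)
  x <- runif(15, 0, 20); y <- 0.8 * x + rnorm(15, 0, 0.5)
  f1 <- repeated_median_fit(x, y, n_boot = 400, seed = 5)
  f2 <- repeated_median_fit(x, y, n_boot = 400, seed = 5)
  expect_identical(f1$ci_low, f2$ci_low)
  expect_true(f1$ci_low <= f1$slope && f1$slope <= f1$ci_high)
  expect_lt(f1$p_value, 0.05)
  expect_error(repeated_median_fit(c(1, 1, 1), 1:3), "distinct")
})

test_that("track summaries collapse the posterior as specified", {
  g <- time_grid()
  tt <- g$onset:g$T
  tr <- make_track(rep(0, 119), 9.25, g)
  start <- start_time_estimate(5, "99", "bayes")

  const <- fake_summary(tt, upper99 = rep(-0.3 + 2, 90), grid = g)
  const$beta$median <- rep(-0.3, 90)
  const$alpha <- data.frame(t = 1:119, median = c(rep(0, 29), rep(-0.3, 90)))
  s1 <- track_summaries(const, start, tr, g)
  expect_equal(s1$mean_coef, -0.3)
  expect_equal(s1$min_coef, -0.3)
  expect_equal(s1$sd_coef, 0)
  expect_equal(s1$d_start, 9.25)

  ramp <- const
  ramp$beta$median <- seq(0, -0.9, length.out = 90)
  ramp$alpha$median <- c(rep(0, 29), ramp$beta$median)
  s2 <- track_summaries(ramp, start, tr, g)
  expect_equal(s2$mean_coef, -0.45)
  expect_equal(s2$min_coef, -0.9)
  expect_equal(s2$min_vel, -0.9)

  # single-draw posterior: sd_coef is that draw's across-time SD exactly
  one <- matrix(seq(0, -0.9, length.out = 90), 1)
  dr <- fake_draws(alpha = matrix(0, 1, 119), beta = one, grid = g)
  s3 <- track_summaries(ramp, start, tr, g, draws = dr)
  expect_equal(s3$sd_coef, sd(one))
})

test_that("signal-speed regression and transfer time follow the definitions", {
  f <- fit_signal_speed(c(5, 10, 20), c(4, 8, 16), "cellA", n_boot = 0)
  expect_equal(f$speed, 0.8)

  expect_equal(fit_signal_speed(c(2, 7, 13, Inf), c(5, 5, 5, 9), n_boot = 0)$speed, 0)
  expect_error(fit_signal_speed(c(5, 10, Inf), c(4, 8, 16), "c"), ">= 3")

  expect_equal(signal_transfer_time(7.7, 0.77), 10)
  expect_equal(signal_transfer_time(0, 0.5), 0)
  expect_equal(signal_transfer_time(12, 1), 12)
  expect_error(signal_transfer_time(5, 0), "positive")

  # recovery under start jitter
  set.seed(75)
  errs <- replicate(8, {
    d0 <- runif(10, 3, 25)
    starts <- d0 / 0.8 + runif(10, -2, 2)
    fit_signal_speed(starts, d0, n_boot = 0)$speed - 0.8
  })
  expect_lt(max(abs(errs)), 0.1)
})

test_that("exact Wilcoxon signed-rank matches enumeration", {
  # 5 pairs, transfer < total in all: p = 1/32
  res <- compare_transfer_vs_total(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$exact)

  # all greater: one-sided "less" p = 1
  res2 <- compare_transfer_vs_total(c(3, 5, 7, 9, 11), c(1, 2, 3, 4, 5))
  expect_equal(res2$p_value, 1)

  # equal pairs: degenerate flag
  res3 <- compare_transfer_vs_total(c(2, 2), c(2, 2))
  expect_true(res3$degenerate)

  # enumeration oracle on random instances including ties
  set.seed(76)
  for (rep in 1:8) {
    n <- sample(4:9, 1)
    x <- sample(seq(0, 3, 0.5), n, replace = TRUE)
    y <- sample(seq(0, 3, 0.5), n, replace = TRUE)
    if (all(x == y)) next
    mine <- wilcoxon_signed_rank(x, y, alternative = "less")
    expect_equal(mine$p_value, oracle_signed_rank_less(x, y))
  }

  # large-n normal approximation stays close to the exact path
  set.seed(77)
  x <- rnorm(40); y <- x + rnorm(40, 0.3)
  appr <- wilcoxon_signed_rank(x, y, alternative = "less")
  exact <- wilcoxon_signed_rank(x, y, alternative = "less", exact_limit = 64)
  expect_false(appr$exact)
  expect_lt(abs(appr$p_value - exact$p_value), 0.01)
})

test_that("exact Fisher test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(4, 0, 0, 4), 2))$p_value, 2 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))$p_value, 1)

  set.seed(78)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})
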