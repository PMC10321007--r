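test_that("posterior summaries use equal-tailed quantiles and nest", {
  g <- time_grid(n_frames = 4, onset = 2)
  # degenerate draws: median equals every bound
  dr <- fake_draws(alpha = matrix(0.7, 5, 3), beta = matrix(0.7, 5, 2), grid = g)
  sm <- summarize_posterior(dr)
  expect_true(all(sm$beta$median == 0.7))
  expect_true(all(sm$beta$lower99 == 0.7 & sm$beta$upper99 == 0.7))

  # standard-normal draws: 99% upper bound near the analytic quantile
  set.seed(30)
  z <- matrix(rnorm(40000), ncol = 2)
  dr2 <- fake_draws(alpha = cbind(z, z[, 1]), beta = z, grid = g)
  sm2 <- summarize_posterior(dr2)
  expect_lt(max(abs(sm2$beta$upper99 - qnorm(0.995))), 0.08)
  expect_lt(max(abs(sm2$beta$lower95 - qnorm(0.025))), 0.05)

  # nesting at every time point
  for (L in list(c(90, 95), c(95, 99))) {
    expect_true(all(sm2$beta[[paste0("lower", L[2])]] <=
                      sm2$beta[[paste0("lower", L[1])]]))
    expect_true(all(sm2$beta[[paste0("upper", L[2])]] >=
                      sm2$beta[[paste0("upper", L[1])]]))
  }
})

test_that("start-time scan implements the 99/95/90 fallback rule", {
  g <- time_grid()
  tt <- g$onset:g$T
  up99 <- rep(1, 90); up99[tt >= 40] <- -0.1
  s1 <- estimate_start_from_intervals(fake_summary(tt, up99), g)
  expect_equal(s1$start_min, 11)
  expect_equal(s1$threshold_used, "99")

  # 99% never negative; 95% first negative at t = 50
  up95 <- rep(1, 90); up95[tt >= 50] <- -0.1
  s2 <- estimate_start_from_intervals(
    fake_summary(tt, upper99 = rep(1, 90), upper95 = up95,
                 upper90 = up95), g)
  expect_equal(s2$start_min, 21)
  expect_equal(s2$threshold_used, "95")

  s3 <- estimate_start_from_intervals(
    fake_summary(tt, upper99 = rep(0.2, 90), upper95 = rep(0.1, 90),
                 upper90 = rep(0.05, 90)), g)
  expect_true(is.infinite(s3$start_min))
  expect_equal(s3$threshold_used, "none")

  # exact zero must not trigger (strictly negative rule)
  up0 <- rep(1, 90); up0[tt >= 60] <- 0
  s4 <- estimate_start_from_intervals(
    fake_summary(tt, upper99 = up0, upper95 = up0, upper90 = up0), g)
  expect_true(is.infinite(s4$start_min))
})

test_that("null data yields null coefficients", {
  g <- time_grid(n_frames = 40, onset = 10)
  dr <- fit_individual(velocity_series(rep(0, g$T), g),
                       individual_model_spec(g, prior_sd_scale = 0.3),
                       mcmc_config(chains = 2, warmup = 200,
                                   samples_per_chain = 200, seed = 3))
  sm <- summarize_posterior(dr)
  expect_true(all(abs(sm$beta$median) < 0.05))
  expect_true(is.infinite(estimate_start_from_intervals(sm, g)$start_min))
})

test_that("sigma-fixed reduction matches the Kalman smoother", {
  # with w removed and all SDs fixed, the collapsed sampler draws beta iid
  # from the exact smoother distribution
  g <- time_grid(n_frames = 31, onset = 11)
  set.seed(31)
  beta_true <- c(rep(0, 5), rep(-0.5, 15))
  y <- c(rnorm(10, 0, 0.3), beta_true + rnorm(20, 0, 0.3))
  vel <- velocity_series(y, g)
  spec <- individual_model_spec(g, fix_sigma_w = 0, fix_sigma_beta = 0.2,
                                fix_sigma_y = 0.3)
  dr <- fit_individual(vel, spec, mcmc_config(chains = 2, warmup = 100,
                                              samples_per_chain = 500, seed = 7))
  or <- oracle_kalman_smoother(g, 0.2^2, 0.3^2, y)
  mc_mean <- colMeans(dr$beta)
  mc_sd <- apply(dr$beta, 2, sd)
  n <- nrow(dr$beta)
  expect_true(all(abs(mc_mean - or$mean) <= 3.5 * sqrt(or$var / n)))
  expect_true(all(abs(mc_sd - sqrt(or$var)) <= 4 * sqrt(or$var / (2 * n))))
})

test_that("MCMC is reproducible given the seed and flags non-convergence", {
  g <- time_grid(n_frames = 30, onset = 10)
  set.seed(33)
  vel <- velocity_series(rnorm(g$T, 0, 0.3), g)
  cfg <- mcmc_config(chains = 2, warmup = 50, samples_per_chain = 50, seed = 12)
  d1 <- fit_individual(vel, individual_model_spec(g), cfg)
  d2 <- fit_individual(vel, individual_model_spec(g), cfg)
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$sigma, d2$sigma)

  # absurd threshold forces the flag
  cfg2 <- mcmc_config(chains = 2, warmup = 50, samples_per_chain = 50,
                      seed = 12, rhat_threshold = 0.5)
  d3 <- fit_individual(vel, individual_model_spec(g), cfg2)
  expect_false(d3$converged)
})

test_that("credible band covers a known pulse at roughly nominal rate", {
  # initial distances exceed the pulse's total displacement (~23 um) so the
  # trajectories never hit the zero floor and the generative beta stays valid
  sim <- simulate_accumulation(sim_params(
    organelles_per_cell = 2, initial_distances = c(25, 30, 27),
    signal_speed = 2.5, seed = 41))
  g <- sim$tracks$grid
  cover <- numeric(0)
  for (i in 1:2) {
    vel <- compute_velocity(sim$tracks$tracks[[i]], g)
    dr <- fit_individual(vel, individual_model_spec(g),
                         mcmc_config(chains = 2, warmup = 300,
                                     samples_per_chain = 300, seed = 50 + i))
    sm <- summarize_posterior(dr)
    truth <- sim$truth$true_beta[[i]][g$onset:g$T]
    cover <- c(cover, truth >= sm$beta$lower95 & truth <= sm$beta$upper95)
  }
  expect_gt(mean(cover), 0.80)   # reduced-rep calibration check
})

test_that("distance reconstruction is the anchored cumulative sum", {
  g <- time_grid(n_frames = 5, onset = 2)
  dr <- fake_draws(alpha = matrix(0, 10, 4), grid = g)
  rec <- reconstruct_distance(dr, d0 = 6.5)
  expect_true(all(rec$median == 6.5))
  expect_true(all(rec$upper99 == 6.5))

  a <- matrix(c(1, -2, 0.5, 3), 1, 4)
  rec1 <- reconstruct_distance(fake_draws(alpha = a, grid = g), d0 = 1)
  expect_equal(rec1$median, c(1, 1 + cumsum(as.vector(a))))
  expect_equal(rec1$upper99, rec1$median)
})
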