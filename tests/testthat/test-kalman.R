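test_that("filter log-likelihood equals the joint-Gaussian oracle", {
  set.seed(21)
  for (rep in 1:6) {
    g <- time_grid(n_frames = 7, onset = sample(2:5, 1))
    s2b <- runif(1, 0.01, 1); s2y <- runif(1, 0.01, 1)
    y <- rnorm(g$T, 0, 0.5)
    m <- kalman_model(g, s2b, s2y)
    expect_equal(kalman_loglik(m, velocity_series(y, g)),
                 oracle_kalman_loglik(g, s2b, s2y, y), tolerance = 1e-10)
  }
})

test_that("smoother equals brute-force Gaussian conditioning", {
  set.seed(22)
  g <- time_grid(n_frames = 7, onset = 3)
  s2b <- 0.2; s2y <- 0.4
  y <- rnorm(g$T, 0, 0.6)
  sm <- smooth_states(kalman_model(g, s2b, s2y), velocity_series(y, g))
  or <- oracle_kalman_smoother(g, s2b, s2y, y)
  expect_equal(sm$states$mean, or$mean, tolerance = 1e-9)
  expect_equal(sm$states$var, or$var, tolerance = 1e-9)
})

test_that("smoother variance never exceeds filter variance", {
  set.seed(23)
  g <- time_grid(n_frames = 40, onset = 10)
  y <- rnorm(g$T, 0, 0.5)
  m <- kalman_model(g, 0.1, 0.3)
  kf <- orgssm:::kalman_filter_core(m, y)
  sm <- smooth_states(m, velocity_series(y, g))
  expect_true(all(sm$states$var <= kf$P_filt + 1e-12))
})

test_that("diffuse constant-mean reduction matches the running-mean predictive", {
  # sigma2_beta = 0 with diffuse init: y[t] = beta0 + e over the beam
  # period; the diffuse filter's loglik equals the one-step predictive
  # decomposition around the running mean, with the first term dropped
  g <- time_grid(n_frames = 16, onset = 6)
  set.seed(24)
  y <- rnorm(g$T, 0.4, 0.5)
  s2y <- 0.3
  ll <- kalman_loglik(kalman_model(g, 0, s2y, diffuse_init = TRUE),
                      velocity_series(y, g))
  post <- y[g$onset:g$T]
  ll_oracle <- sum(dnorm(y[1:(g$onset - 1)], 0, sqrt(s2y), log = TRUE))
  for (j in 2:length(post)) {
    mu <- mean(post[1:(j - 1)])
    ll_oracle <- ll_oracle +
      dnorm(post[j], mu, sqrt(s2y * (1 + 1 / (j - 1))), log = TRUE)
  }
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("single post-onset point gives the closed-form likelihood", {
  g <- time_grid(n_frames = 8, onset = 7)
  y <- c(rep(0, 6), 0.9)
  s2b <- 0.5
  for (s2y in c(0.2, 0.8)) {
    ll <- kalman_loglik(kalman_model(g, s2b, s2y), velocity_series(y, g))
    expect_equal(ll, sum(dnorm(rep(0, 6), 0, sqrt(s2y), log = TRUE)) +
                   dnorm(0.9, 0, sqrt(s2b + s2y), log = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("variance MLE recovers simulated truth and responds monotonically", {
  g <- time_grid()
  s2b_true <- 0.05^2 * 4  # modest random walk
  s2y_true <- 0.3^2
  set.seed(25)
  est <- replicate(6, {
    beta <- cumsum(rnorm(90, 0, sqrt(s2b_true)))
    y <- c(rnorm(29, 0, sqrt(s2y_true)), beta + rnorm(90, 0, sqrt(s2y_true)))
    m <- fit_variances_mle(velocity_series(y, g), g)
    log(c(m$sigma2_beta, m$sigma2_y))
  })
  expect_lt(abs(mean(est[1, ]) - log(s2b_true)), 0.6)
  expect_lt(abs(mean(est[2, ]) - log(s2y_true)), 0.3)

  # doubling the pre-onset noise must raise the fitted observation variance
  set.seed(26)
  y <- c(rnorm(29, 0, 0.3), cumsum(rnorm(90, 0, 0.1)) + rnorm(90, 0, 0.3))
  y2 <- y; y2[1:29] <- 2 * y2[1:29]
  f1 <- fit_variances_mle(velocity_series(y, g), g)
  f2 <- fit_variances_mle(velocity_series(y2, g), g)
  expect_gt(f2$sigma2_y, f1$sigma2_y)

  # no random walk in truth: fitted s2b collapses toward the boundary
  set.seed(27)
  y0 <- rnorm(g$T, 0, 0.3)
  f0 <- fit_variances_mle(velocity_series(y0, g), g)
  expect_lt(f0$sigma2_beta, 0.005)
  expect_true(attr(f0, "converged"))
})

test_that("smoothed coefficient tracks a noiseless linear decline", {
  g <- time_grid()
  y <- c(rep(0, 29), rep(-0.4, 90))      # constant approach speed post-onset
  sm <- smooth_states(kalman_model(g, 1e-6, 1e-6, diffuse_init = TRUE),
                      velocity_series(y, g))
  expect_true(all(abs(sm$states$mean - (-0.4)) < 1e-3))

  # zero data: zero smoothed coefficient, symmetric intervals
  sm0 <- smooth_states(kalman_model(g, 0.1, 0.1),
                       velocity_series(rep(0, g$T), g))
  expect_true(all(abs(sm0$states$mean) < 1e-12))
  ks <- kalman_summary(sm0)
  expect_equal(ks$beta$upper99, -ks$beta$lower99)
})

test_that("kalman start detection follows the interval scan", {
  # simulated accumulation with a clear pulse: detector returns a finite,
  # plausible start and the same scan applied at 95% starts no later
  sim <- simulate_accumulation(sim_params(organelles_per_cell = 1,
                                          initial_distances = 10,
                                          seed = 14))
  g <- sim$tracks$grid
  vel <- compute_velocity(sim$tracks$tracks[[1]], g)
  k <- detect_start_kalman(vel, g)
  expect_true(is.finite(k$start$start_min))
  true_start <- sim$truth$per_organelle$true_start_min
  expect_lt(abs(k$start$start_min - true_start), 8)
})
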