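# Independent oracles used to check the package's own implementations.
# These deliberately take the brute-force route (joint covariance matrices,
# explicit loops, enumeration) rather than the filtering / vectorised code
# paths they validate.

# Multivariate normal log-density at x for mean 0 and covariance Sigma.
mvn_logdens <- function(x, Sigma) {
  U <- chol(Sigma)
  z <- backsolve(U, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

# Joint covariance of the observed velocities under the Kalman-variant
# model (no white noise): pre-onset iid N(0, s2y); post-onset y = beta + e
# with beta a random walk started at N(0, s2b), so
# Cov(y_s, y_t) = s2b * (min(s,t) - onset + 1) + s2y * 1{s == t}.
kalman_joint_cov <- function(grid, s2b, s2y) {
  T_ <- grid$T; t0 <- grid$onset
  Sigma <- diag(s2y, T_)
  post <- t0:T_
  for (s in post) for (t in post) {
    Sigma[s, t] <- Sigma[s, t] + s2b * (min(s, t) - t0 + 1)
  }
  Sigma
}

# Brute-force log-likelihood via the assembled joint Gaussian.
oracle_kalman_loglik <- function(grid, s2b, s2y, y) {
  mvn_logdens(y, kalman_joint_cov(grid, s2b, s2y))
}

# Brute-force smoothed means/variances of beta[t] by Gaussian conditioning:
# beta | y ~ N(C S^-1 y, V - C S^-1 C') with C = Cov(beta, y).
oracle_kalman_smoother <- function(grid, s2b, s2y, y) {
  T_ <- grid$T; t0 <- grid$onset
  post <- t0:T_
  Sigma <- kalman_joint_cov(grid, s2b, s2y)
  # Cov(beta_s, y_t) = s2b * min(s,t) counted from onset, for t in post
  C <- matrix(0, length(post), T_)
  for (i in seq_along(post)) for (t in post) {
    C[i, t] <- s2b * (min(post[i], t) - t0 + 1)
  }
  Vb <- outer(post, post, function(s, t) s2b * (pmin(s, t) - t0 + 1))
  K <- C %*% solve(Sigma)
  list(mean = as.vector(K %*% y), var = diag(Vb - K %*% t(C)))
}

# Repeated-median slope/intercept by explicit loops.
oracle_repeated_median <- function(x, y) {
  n <- length(x)
  inner <- numeric(n)
  for (i in seq_len(n)) {
    sl <- c()
    for (j in seq_len(n)) {
      if (j != i && x[j] != x[i]) sl <- c(sl, (y[j] - y[i]) / (x[j] - x[i]))
    }
    inner[i] <- median(sl)
  }
  slope <- median(inner)
  c(slope = slope, intercept = median(y - slope * x))
}

# One-sided ("less") exact signed-rank p-value by enumeration of all 2^n
# sign patterns (ties handled through the same mid-ranks the test uses).
oracle_signed_rank_less <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    if (sum(r[signs == 1]) <= V_obs) count <- count + 1L
  }
  count / 2^n
}

# Small deterministic track builder: distances from a velocity vector.
make_track <- function(y, d0, grid, cell = "c1", org = "o1") {
  cell_track(cell, org, c(d0, d0 + cumsum(y)), grid)
}

# Fake posterior_summary with given beta bounds (for the start-time scan).
fake_summary <- function(t, upper99, upper95 = upper99, upper90 = upper95,
                         grid = time_grid(), method = "bayes") {
  beta <- data.frame(t = t, median = upper99 - 1,
                     lower90 = upper90 - 2, upper90 = upper90,
                     lower95 = upper95 - 2, upper95 = upper95,
                     lower99 = upper99 - 2, upper99 = upper99)
  structure(list(beta = beta, alpha = NULL, w = NULL,
                 sigma = c(sigma_w = 0, sigma_beta = 0, sigma_y = 0),
                 levels = c(90, 95, 99), grid = grid, method = method),
            class = "posterior_summary")
}

# Fake posterior_draws from explicit alpha/beta matrices.
fake_draws <- function(alpha, beta = NULL, grid = time_grid()) {
  colnames(alpha) <- seq_len(ncol(alpha))
  if (!is.null(beta)) colnames(beta) <- grid$onset:grid$T
  structure(list(beta = beta, alpha = alpha, w = NULL,
                 sigma = matrix(0, nrow(alpha), 3,
                                dimnames = list(NULL, c("sigma_w", "sigma_beta", "sigma_y"))),
                 chain_id = rep(1L, nrow(alpha)),
                 rhat = list(max = 1), converged = TRUE, grid = grid,
                 method = "bayes"),
            class = "posterior_draws")
}
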