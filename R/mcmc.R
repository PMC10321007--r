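# MCMC machinery for the linear-Gaussian state-space models.
#
# Both the individual model (one organelle, its own stimulus coefficient)
# and the per-cell common model (N organelles sharing one white-noise series
# and one time-shifted coefficient trajectory) are conditionally Gaussian:
# given the three SDs, the latent states (w[1..T], beta[onset..T]) have a
# multivariate normal posterior with sparse precision. The sampler therefore
# alternates an exact joint draw of the states (dense Cholesky; dimension is
# at most T + S ~ 209 for the default grid) with univariate slice updates of
# the log-SDs under half-Normal(0, prior_sd_scale) priors.

#' MCMC settings
#'
#' @param chains Number of independent chains (default 4).
#' @param warmup Warm-up (discarded) iterations per chain (default 1000).
#' @param samples_per_chain Retained draws per chain (default 1000).
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @param rhat_threshold Split R-hat above which a fit is flagged as
#'   non-converged (default 1.1).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, warmup = 1000L, samples_per_chain = 1000L,
                        seed = 1L, rhat_threshold = 1.1) {
  stopifnot(chains >= 1, warmup >= 1, samples_per_chain >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples_per_chain = as.integer(samples_per_chain),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

# Univariate slice sampler (Neal 2003, stepping out + shrinkage) on an
# unnormalised log density. Deterministic under the ambient RNG state.
slice_sample_1d <- function(logf, x0, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# log conditional of theta = log(sigma) given a Gaussian sum of squares:
# n terms N(0, sigma^2), SS = sum of squares, half-Normal(0, s0) prior on
# sigma, plus the log-Jacobian of the log transform.
log_sigma_cond <- function(theta, n, SS, s0) {
  s2 <- exp(2 * theta)
  -n * theta - SS / (2 * s2) - s2 / (2 * s0^2) + theta
}

update_log_sigma <- function(theta, n, SS, s0) {
  slice_sample_1d(function(th) log_sigma_cond(th, n, SS, s0), theta, w = 0.5)
}

# Random-walk prior precision pattern for beta[onset..T] (Eq.-style proper
# initialisation beta[onset] ~ N(0, sigma_beta^2)): tridiagonal matrix M such
# that the prior precision is M / sigma_beta^2.
rw_precision_pattern <- function(S) {
  if (S == 1L) return(matrix(1, 1, 1))
  M <- diag(c(rep(2, S - 1L), 1))
  for (j in seq_len(S - 1L)) { M[j, j + 1L] <- -1; M[j + 1L, j] <- -1 }
  M
}

# Build the fixed observation design for the stacked model.
# Y: T x N velocity matrix. t_first[n]: absolute velocity index at which
# organelle n's coefficient trajectory begins (>= grid$onset); at t >= t_first
# the observation loads beta[t - t_first[n] + onset]. has_w: include the
# shared white-noise states.
build_design <- function(Y, t_first, grid, has_w) {
  T_ <- grid$T; S <- T_ - grid$onset + 1L; N <- ncol(Y)
  p_w <- if (has_w) T_ else 0L
  p <- p_w + S
  nobs <- T_ * N
  A <- matrix(0, nobs, p)
  row <- 0L
  for (n in seq_len(N)) {
    for (t in seq_len(T_)) {
      row <- row + 1L
      if (has_w) A[row, t] <- 1
      if (t >= t_first[n]) {
        j <- t - t_first[n] + 1L   # position in beta block (1 == onset)
        A[row, p_w + j] <- 1
      }
    }
  }
  list(A = A, AtA = crossprod(A), Aty = as.vector(crossprod(A, as.vector(Y))),
       yvec = as.vector(Y), p_w = p_w, S = S, p = p, nobs = nobs)
}

# One chain of the Gibbs sampler for the stacked (N >= 2) model: exact joint
# (w, beta) draw given the SDs, then slice updates of the log-SDs. fix: list
# with optional numeric entries sigma_w, sigma_beta, sigma_y (fixing
# sigma_w = 0 removes the w states).
run_chain_joint <- function(des, Mbeta, grid, prior_sd_scale, fix, n_iter, keep, seed) {
  set.seed(seed)
  p_w <- des$p_w; S <- des$S; p <- des$p
  has_w <- p_w > 0L
  s0 <- prior_sd_scale

  sd_or <- function(nm, default) if (!is.null(fix[[nm]])) fix[[nm]] else default
  sigma_w <- sd_or("sigma_w", if (has_w) s0 / 2 else 0)
  sigma_beta <- sd_or("sigma_beta", s0 / 2)
  sigma_y <- sd_or("sigma_y", s0 / 2)
  th_w <- if (has_w && sigma_w > 0) log(sigma_w) else -Inf
  th_b <- log(sigma_beta); th_y <- log(sigma_y)

  n_keep <- sum(keep)
  beta_draws <- matrix(NA_real_, n_keep, S)
  w_draws <- if (has_w) matrix(NA_real_, n_keep, p_w) else NULL
  sigma_draws <- matrix(NA_real_, n_keep, 3,
                        dimnames = list(NULL, c("sigma_w", "sigma_beta", "sigma_y")))
  kept <- 0L
  P0 <- matrix(0, p, p)
  bidx <- (p_w + 1L):p
  for (it in seq_len(n_iter)) {
    # exact joint state draw given SDs
    P0[] <- 0
    if (has_w) diag(P0)[seq_len(p_w)] <- 1 / sigma_w^2
    P0[bidx, bidx] <- Mbeta / sigma_beta^2
    Q <- P0 + des$AtA / sigma_y^2
    U <- chol(Q)
    mu <- backsolve(U, forwardsolve(t(U), des$Aty / sigma_y^2))
    x <- mu + backsolve(U, stats::rnorm(p))
    w <- if (has_w) x[seq_len(p_w)] else numeric(0)
    beta <- x[bidx]

    # SD updates by slice sampling on the log scale
    if (has_w && is.null(fix$sigma_w)) {
      th_w <- update_log_sigma(th_w, p_w, sum(w^2), s0)
      sigma_w <- exp(th_w)
    }
    if (is.null(fix$sigma_beta)) {
      incr <- c(beta[1L], diff(beta))
      th_b <- update_log_sigma(th_b, S, sum(incr^2), s0)
      sigma_beta <- exp(th_b)
    }
    if (is.null(fix$sigma_y)) {
      resid <- des$yvec - as.vector(des$A %*% x)
      th_y <- update_log_sigma(th_y, des$nobs, sum(resid^2), s0)
      sigma_y <- exp(th_y)
    }

    if (keep[it]) {
      kept <- kept + 1L
      beta_draws[kept, ] <- beta
      if (has_w) w_draws[kept, ] <- w
      sigma_draws[kept, ] <- c(sigma_w, sigma_beta, sigma_y)
    }
  }
  list(beta = beta_draws, w = w_draws, sigma = sigma_draws)
}

# One chain of the collapsed sampler for a single organelle. With N = 1 the
# white noise w and the observation error are only jointly identified
# (they enter the likelihood through sigma_w^2 + sigma_y^2 alone), so the
# joint Gibbs scheme mixes poorly along that ridge. Here w is integrated
# out: beta is drawn against observation variance s2 = sigma_w^2 +
# sigma_y^2, the two SDs are slice-sampled against that marginal
# likelihood (their split is then prior-driven, as it must be), and w is
# redrawn from its exact conditional for output only.
run_chain_collapsed <- function(des, Mbeta, grid, prior_sd_scale, fix,
                                n_iter, keep, seed) {
  set.seed(seed)
  S <- des$S
  T_ <- grid$T
  s0 <- prior_sd_scale
  has_w <- is.null(fix$sigma_w) || fix$sigma_w > 0

  sd_or <- function(nm, default) if (!is.null(fix[[nm]])) fix[[nm]] else default
  sigma_w <- sd_or("sigma_w", if (has_w) s0 / 2 else 0)
  sigma_beta <- sd_or("sigma_beta", s0 / 2)
  sigma_y <- sd_or("sigma_y", s0 / 2)
  th_b <- log(sigma_beta)

  # marginal log-conditional of one log-SD given the other, from the
  # T residual terms N(0, sigma_w^2 + sigma_y^2) plus prior and Jacobian
  log_sd_marg <- function(th, other_sd, SS) {
    sd_ <- exp(th)
    s2 <- sd_^2 + other_sd^2
    -T_ / 2 * log(s2) - SS / (2 * s2) - sd_^2 / (2 * s0^2) + th
  }

  n_keep <- sum(keep)
  beta_draws <- matrix(NA_real_, n_keep, S)
  w_draws <- if (has_w) matrix(NA_real_, n_keep, T_) else NULL
  sigma_draws <- matrix(NA_real_, n_keep, 3,
                        dimnames = list(NULL, c("sigma_w", "sigma_beta", "sigma_y")))
  kept <- 0L
  for (it in seq_len(n_iter)) {
    s2 <- sigma_w^2 + sigma_y^2
    Q <- Mbeta / sigma_beta^2 + des$AtA / s2
    U <- chol(Q)
    mu <- backsolve(U, forwardsolve(t(U), des$Aty / s2))
    beta <- mu + backsolve(U, stats::rnorm(S))

    resid <- des$yvec - as.vector(des$A %*% beta)
    SS_m <- sum(resid^2)
    if (has_w && is.null(fix$sigma_w)) {
      sigma_w <- exp(slice_sample_1d(function(th)
        log_sd_marg(th, sigma_y, SS_m), log(sigma_w), w = 0.5))
    }
    if (is.null(fix$sigma_y)) {
      sigma_y <- exp(slice_sample_1d(function(th)
        log_sd_marg(th, sigma_w, SS_m), log(sigma_y), w = 0.5))
    }
    if (is.null(fix$sigma_beta)) {
      incr <- c(beta[1L], diff(beta))
      th_b <- update_log_sigma(th_b, S, sum(incr^2), s0)
      sigma_beta <- exp(th_b)
    }

    if (keep[it]) {
      kept <- kept + 1L
      beta_draws[kept, ] <- beta
      if (has_w) {
        v <- 1 / (1 / sigma_w^2 + 1 / sigma_y^2)
        w_draws[kept, ] <- stats::rnorm(T_, v * resid / sigma_y^2, sqrt(v))
      }
      sigma_draws[kept, ] <- c(sigma_w, sigma_beta, sigma_y)
    }
  }
  list(beta = beta_draws, w = w_draws, sigma = sigma_draws)
}

# Split R-hat (Gelman et al.) for a draws matrix with a chain index vector.
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(seq_along(x), chain), function(idx) {
    h <- rep(1:2, each = ceiling(length(idx) / 2))[seq_along(idx)]
    paste(chain[idx[1L]], h)
  }))
  grp <- split(x, halves)
  m <- length(grp); n <- min(lengths(grp))
  grp <- lapply(grp, function(g) g[seq_len(n)])
  means <- vapply(grp, mean, numeric(1))
  vars <- vapply(grp, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Fit the stacked linear-Gaussian model by MCMC. Returns raw draws plus
# diagnostics; shared by fit_individual() and fit_common().
fit_lgssm_mcmc <- function(Y, t_first, grid, prior_sd_scale, fix, mcmc) {
  stopifnot(inherits(grid, "time_grid"), inherits(mcmc, "mcmc_config"))
  Y <- as.matrix(Y)
  if (nrow(Y) != grid$T) stop("velocity matrix must have grid$T rows")
  if (any(t_first < grid$onset | t_first > grid$T)) {
    stop("t_first must lie in onset..T")
  }
  has_w <- is.null(fix$sigma_w) || fix$sigma_w > 0
  if (!is.null(fix$sigma_w) && fix$sigma_w == 0) has_w <- FALSE
  collapsed <- ncol(Y) == 1L          # w enters a single likelihood ridge
  des <- build_design(Y, t_first, grid, has_w && !collapsed)
  Mbeta <- rw_precision_pattern(des$S)
  n_iter <- mcmc$warmup + mcmc$samples_per_chain
  keep <- c(rep(FALSE, mcmc$warmup), rep(TRUE, mcmc$samples_per_chain))
  chain_seeds <- (as.double(mcmc$seed) * 2654435761 + seq_len(mcmc$chains) * 40503) %% 2147483629 + 1

  runner <- if (collapsed) run_chain_collapsed else run_chain_joint
  res <- lapply(seq_len(mcmc$chains), function(ch) {
    runner(des, Mbeta, grid, prior_sd_scale, fix, n_iter, keep, chain_seeds[ch])
  })
  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  w <- if (has_w) do.call(rbind, lapply(res, `[[`, "w")) else NULL
  sigma <- do.call(rbind, lapply(res, `[[`, "sigma"))
  chain_id <- rep(seq_len(mcmc$chains), each = mcmc$samples_per_chain)

  rhat_sigma <- vapply(colnames(sigma), function(cn) {
    if (stats::sd(sigma[, cn]) == 0) NA_real_ else split_rhat(sigma[, cn], chain_id)
  }, numeric(1))
  rhat_beta <- apply(beta, 2, function(col) {
    if (stats::sd(col) == 0) NA_real_ else split_rhat(col, chain_id)
  })
  rhat_max <- suppressWarnings(max(c(rhat_sigma, rhat_beta), na.rm = TRUE))
  converged <- is.finite(rhat_max) && rhat_max <= mcmc$rhat_threshold

  list(beta = beta, w = w, sigma = sigma, chain_id = chain_id,
       rhat = list(sigma = rhat_sigma, beta = rhat_beta, max = rhat_max),
       converged = converged, has_w = has_w, grid = grid, t_first = t_first)
}
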