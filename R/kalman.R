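#' Kalman-filter variant of the individual model
#'
#' Drops the white-noise velocity term: pre-onset velocities are iid
#' `N(0, sigma2_y)`, and from stimulus onset `y[t] = beta[t] + e[t]` with
#' `beta` a Gaussian random walk (innovation variance `sigma2_beta`,
#' initialised at `N(0, sigma2_beta)` unless `diffuse_init`). The model is
#' linear-Gaussian, so the likelihood and the smoothed coefficient are exact.
#'
#' @param grid A [time_grid()].
#' @param sigma2_beta Random-walk innovation variance ((um/min)^2).
#' @param sigma2_y Observation variance ((um/min)^2).
#' @param diffuse_init Use a diffuse initial distribution for the
#'   coefficient instead of the proper `N(0, sigma2_beta)` (default FALSE).
#' @return An object of class `kalman_model`.
#' @export
kalman_model <- function(grid = time_grid(), sigma2_beta, sigma2_y,
                         diffuse_init = FALSE) {
  stopifnot(inherits(grid, "time_grid"))
  if (sigma2_beta < 0 || sigma2_y < 0) stop("variances must be >= 0")
  if (sigma2_beta == 0 && sigma2_y == 0) stop("variances must not both be 0")
  structure(list(grid = grid, sigma2_beta = sigma2_beta, sigma2_y = sigma2_y,
                 diffuse_init = isTRUE(diffuse_init)),
            class = "kalman_model")
}

# Scalar Kalman filter over the beam period. Returns filtered/predicted
# moments and the log-likelihood (pre-onset iid terms included; the first
# beam-period term is dropped under diffuse initialisation).
kalman_filter_core <- function(model, y) {
  g <- model$grid
  T_ <- g$T; t0 <- g$onset
  s2b <- model$sigma2_beta; s2y <- model$sigma2_y
  ll <- 0
  if (t0 > 1L) {
    pre <- y[seq_len(t0 - 1L)]
    if (s2y == 0) {
      ll <- if (all(pre == 0)) 0 else -Inf
    } else {
      ll <- sum(stats::dnorm(pre, 0, sqrt(s2y), log = TRUE))
    }
  }
  S <- T_ - t0 + 1L
  a_pred <- numeric(S); P_pred <- numeric(S)     # beta[t] | y[1..t-1]
  a_filt <- numeric(S); P_filt <- numeric(S)     # beta[t] | y[1..t]
  a <- 0
  P <- if (model$diffuse_init) Inf else s2b
  for (j in seq_len(S)) {
    a_pred[j] <- a; P_pred[j] <- P
    v <- y[t0 + j - 1L] - a
    if (is.infinite(P)) {                        # exact diffuse first step
      a <- y[t0 + j - 1L]; P <- s2y
    } else {
      F_ <- P + s2y
      if (F_ <= 0) {
        ll <- ll + if (abs(v) < 1e-12) 0 else -Inf
        # degenerate: observation is exact
        a <- y[t0 + j - 1L]; P <- 0
      } else {
        ll <- ll + stats::dnorm(v, 0, sqrt(F_), log = TRUE)
        K <- P / F_
        a <- a + K * v
        P <- (1 - K) * P
      }
    }
    a_filt[j] <- a; P_filt[j] <- P
    a <- a; P <- P + s2b                         # random-walk prediction
  }
  list(loglik = ll, a_pred = a_pred, P_pred = P_pred,
       a_filt = a_filt, P_filt = P_filt)
}

#' Exact Gaussian log-likelihood of the Kalman model
#'
#' @param model A [kalman_model()].
#' @param velocity A [velocity_series()] on the same grid.
#' @return Log-likelihood (scalar).
#' @export
kalman_loglik <- function(model, velocity) {
  stopifnot(inherits(model, "kalman_model"), inherits(velocity, "velocity_series"))
  y <- velocity$y
  if (length(y) != model$grid$T) stop("velocity does not match model grid")
  if (any(!is.finite(y))) stop("velocities must be finite")
  kalman_filter_core(model, y)$loglik
}

#' Maximum-likelihood variance estimation for the Kalman model
#'
#' Maximises [kalman_loglik()] over `(log sigma2_beta, log sigma2_y)` by
#' Nelder-Mead from three data-driven starts (guarding against boundary
#' optima); the best optimum wins.
#'
#' @param velocity A [velocity_series()].
#' @param grid A [time_grid()].
#' @param diffuse_init Passed to [kalman_model()].
#' @return A [kalman_model()] with attributes `loglik` and `converged`.
#' @export
fit_variances_mle <- function(velocity, grid = velocity$grid,
                              diffuse_init = FALSE) {
  stopifnot(inherits(velocity, "velocity_series"), inherits(grid, "time_grid"))
  y <- velocity$y
  if (grid$T - grid$onset + 1L < 10L) {
    stop("need at least 10 post-onset velocity points")
  }
  v_pre <- stats::var(y[seq_len(grid$onset - 1L)])
  if (!is.finite(v_pre) || v_pre <= 0) v_pre <- max(stats::var(y), 1e-4)
  v_diff <- stats::var(diff(y[grid$onset:grid$T])) / 2
  if (!is.finite(v_diff) || v_diff <= 0) v_diff <- v_pre / 10
  starts <- list(log(c(v_diff, v_pre)),
                 log(c(v_diff / 25, v_pre * 2)),
                 log(c(v_diff * 4, v_pre / 4)))
  nll <- function(par) {
    m <- kalman_model(grid, exp(par[1]), exp(par[2]), diffuse_init)
    ll <- kalman_filter_core(m, y)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, nll, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  model <- kalman_model(grid, exp(best$par[1]), exp(best$par[2]), diffuse_init)
  attr(model, "loglik") <- -best$value
  attr(model, "converged") <- best$convergence == 0
  model
}

#' Fixed-interval smoothing of the stimulus coefficient
#'
#' Runs the Kalman filter and the Rauch-Tung-Striebel smoother, returning
#' smoothed means and variances of `beta[t]` over the beam period, the
#' fitted observation mean, and the log-likelihood.
#'
#' @param model A [kalman_model()] (typically from [fit_variances_mle()]).
#' @param velocity A [velocity_series()].
#' @return An object of class `smoothed_states`: data frame `states` with
#'   `t`, `mean`, `var`; vector `fitted` (length `grid$T`); `loglik`;
#'   `model`.
#' @export
smooth_states <- function(model, velocity) {
  stopifnot(inherits(model, "kalman_model"), inherits(velocity, "velocity_series"))
  g <- model$grid
  y <- velocity$y
  if (length(y) != g$T) stop("velocity does not match model grid")
  kf <- kalman_filter_core(model, y)
  S <- g$T - g$onset + 1L
  m <- numeric(S); V <- numeric(S)
  m[S] <- kf$a_filt[S]; V[S] <- kf$P_filt[S]
  if (S > 1L) {
    for (j in (S - 1L):1L) {
      P_next_pred <- kf$P_filt[j] + model$sigma2_beta
      h <- if (P_next_pred > 0) kf$P_filt[j] / P_next_pred else 0
      m[j] <- kf$a_filt[j] + h * (m[j + 1L] - kf$a_filt[j])
      V[j] <- kf$P_filt[j] + h^2 * (V[j + 1L] - P_next_pred)
      V[j] <- max(V[j], 0)
    }
  }
  fitted <- numeric(g$T)
  fitted[g$onset:g$T] <- m
  structure(list(states = data.frame(t = g$onset:g$T, mean = m, var = V),
                 fitted = fitted, loglik = kf$loglik, model = model),
            class = "smoothed_states")
}

#' Gaussian interval summary of smoothed states
#'
#' Converts smoothed means/variances into the same `posterior_summary`
#' layout the Bayesian route produces (level-L bounds are
#' `mean +/- z_(1+L/100)/2 * SD`), so [estimate_start_from_intervals()] can
#' be reused unchanged.
#'
#' @param sm A [smooth_states()] result.
#' @param levels Interval levels, default `c(90, 95, 99)`.
#' @return A `posterior_summary` with `method = "kalman"`.
#' @export
kalman_summary <- function(sm, levels = c(90, 95, 99)) {
  stopifnot(inherits(sm, "smoothed_states"))
  levels <- sort(as.numeric(levels))
  st <- sm$states
  sd_ <- sqrt(st$var)
  beta <- data.frame(t = st$t, median = st$mean)
  for (L in levels) {
    z <- stats::qnorm((1 + L / 100) / 2)
    beta[[paste0("lower", L)]] <- st$mean - z * sd_
    beta[[paste0("upper", L)]] <- st$mean + z * sd_
  }
  g <- sm$model$grid
  alpha <- beta
  alpha$t <- NULL
  pre <- data.frame(t = seq_len(g$onset - 1L), median = 0)
  for (L in levels) { pre[[paste0("lower", L)]] <- 0; pre[[paste0("upper", L)]] <- 0 }
  alpha <- rbind(pre, cbind(data.frame(t = st$t), alpha))
  structure(list(beta = beta, alpha = alpha, w = NULL,
                 sigma = c(sigma_w = 0,
                           sigma_beta = sqrt(sm$model$sigma2_beta),
                           sigma_y = sqrt(sm$model$sigma2_y)),
                 levels = levels, grid = g, method = "kalman"),
            class = "posterior_summary")
}

#' One-call Kalman start-time detector
#'
#' Fits the variances by maximum likelihood, smooths, and applies the
#' 99/95/90 upper-bound scan.
#'
#' @param velocity A [velocity_series()].
#' @param grid A [time_grid()].
#' @param diffuse_init Passed to [kalman_model()].
#' @param direction `"approach"` or `"escape"`, passed to
#'   [estimate_start_from_intervals()].
#' @return A list with `start` (a [start_time_estimate()]), `summary`,
#'   `smoothed`, and the fitted `model`.
#' @export
detect_start_kalman <- function(velocity, grid = velocity$grid,
                                diffuse_init = FALSE,
                                direction = c("approach", "escape")) {
  model <- fit_variances_mle(velocity, grid, diffuse_init)
  sm <- smooth_states(model, velocity)
  summ <- kalman_summary(sm)
  list(start = estimate_start_from_intervals(summ, grid, direction),
       summary = summ, smoothed = sm, model = model)
}
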