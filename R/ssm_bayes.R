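#' Individual-model specification
#'
#' The individual model explains an organelle's observed velocity `y[t]` as
#' `y[t] ~ N(alpha[t], sigma_y^2)` with `alpha[t] = w[t]` before stimulus
#' onset and `alpha[t] = w[t] + beta[t]` from onset, where `w[t] ~ N(0,
#' sigma_w^2)` is white noise and `beta[t]` (the time-varying stimulus
#' coefficient) follows a Gaussian random walk started at `N(0,
#' sigma_beta^2)`. All three SDs get half-Normal(0, `prior_sd_scale`)
#' priors.
#'
#' `fix_*` entries pin an SD to a known value instead of sampling it;
#' `fix_sigma_w = 0` removes the white-noise states entirely, reducing the
#' model to the Kalman-filter variant's likelihood (useful for
#' cross-validation between the two routes).
#'
#' @param grid A [time_grid()].
#' @param prior_sd_scale Scale (um/min) of the half-Normal priors, default 1.
#' @param fix_sigma_w,fix_sigma_beta,fix_sigma_y Optional fixed SD values.
#' @return An object of class `individual_model_spec`.
#' @export
individual_model_spec <- function(grid = time_grid(), prior_sd_scale = 1,
                                  fix_sigma_w = NULL, fix_sigma_beta = NULL,
                                  fix_sigma_y = NULL) {
  stopifnot(inherits(grid, "time_grid"), prior_sd_scale > 0)
  structure(list(grid = grid, prior_sd_scale = prior_sd_scale,
                 fix = list(sigma_w = fix_sigma_w, sigma_beta = fix_sigma_beta,
                            sigma_y = fix_sigma_y)),
            class = "individual_model_spec")
}

# Assemble alpha draws (true velocity state) from beta/w draws for a single
# organelle whose coefficient starts at absolute index t_first.
alpha_from_draws <- function(beta, w, t_first, grid) {
  T_ <- grid$T
  n_draws <- nrow(beta)
  alpha <- if (is.null(w)) matrix(0, n_draws, T_) else w
  idx <- t_first:T_
  alpha[, idx] <- alpha[, idx, drop = FALSE] + beta[, seq_along(idx), drop = FALSE]
  colnames(alpha) <- seq_len(T_)
  alpha
}

#' Fit the Bayesian individual model to one velocity series
#'
#' Draws from the joint posterior of the latent states and the three SDs by
#' a Gibbs sampler: exact multivariate-Gaussian state draws given the SDs,
#' slice-sampling of the log-SDs given the states. Convergence is summarised
#' by split R-hat; a fit whose maximum R-hat exceeds the configured
#' threshold is returned with `converged = FALSE` (never a silent failure).
#'
#' @param velocity A [velocity_series()] (or [compute_velocity()] output).
#' @param spec An [individual_model_spec()] on the same grid.
#' @param mcmc An [mcmc_config()].
#' @return An object of class `posterior_draws` with matrices `beta`
#'   (draws x beam-period time points, columns named by velocity index),
#'   `alpha`, `w` (NULL when the white-noise states are fixed out), `sigma`
#'   (draws x 3), plus `chain_id`, `rhat`, `converged`, `grid`, `method`.
#' @export
fit_individual <- function(velocity, spec, mcmc = mcmc_config()) {
  stopifnot(inherits(velocity, "velocity_series"),
            inherits(spec, "individual_model_spec"))
  grid <- spec$grid
  if (length(velocity$y) != grid$T) stop("velocity does not match spec grid")
  fit <- fit_lgssm_mcmc(matrix(velocity$y, ncol = 1), t_first = grid$onset,
                        grid = grid, prior_sd_scale = spec$prior_sd_scale,
                        fix = spec$fix, mcmc = mcmc)
  beta <- fit$beta
  colnames(beta) <- grid$onset:grid$T
  alpha <- alpha_from_draws(beta, fit$w, grid$onset, grid)
  if (!is.null(fit$w)) colnames(fit$w) <- seq_len(grid$T)
  structure(list(beta = beta, alpha = alpha, w = fit$w, sigma = fit$sigma,
                 chain_id = fit$chain_id, rhat = fit$rhat,
                 converged = fit$converged, grid = grid, method = "bayes"),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws, %d beam-period points, max R-hat %.3f%s\n",
              nrow(x$beta), ncol(x$beta), x$rhat$max,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

quantile_cols <- function(mat, levels) {
  probs <- c(0.5, unlist(lapply(levels, function(L) {
    a <- (1 - L / 100) / 2
    c(a, 1 - a)
  })))
  qs <- t(apply(mat, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(median = qs[, 1])
  for (i in seq_along(levels)) {
    out[[paste0("lower", levels[i])]] <- qs[, 2 * i]
    out[[paste0("upper", levels[i])]] <- qs[, 2 * i + 1]
  }
  out
}

#' Summarise posterior draws as medians and central intervals
#'
#' Equal-tailed central intervals: level L uses the `(1 - L/100)/2` and
#' `1 - (1 - L/100)/2` quantiles, so e.g. the "99% upper bound" is the 0.995
#' posterior quantile. Intervals at increasing levels are nested by
#' quantile monotonicity.
#'
#' @param draws A `posterior_draws` (from [fit_individual()] or
#'   [fit_common()]).
#' @param levels Interval levels in percent (default `c(90, 95, 99)`).
#' @return An object of class `posterior_summary`: data frames `beta`,
#'   `alpha` and (if present) `w`, each with columns `t`, `median`,
#'   `lower<L>`/`upper<L>` per level; plus `sigma` posterior medians.
#' @export
summarize_posterior <- function(draws, levels = c(90, 95, 99)) {
  stopifnot(inherits(draws, "posterior_draws"))
  levels <- sort(as.numeric(levels))
  if (!length(levels) || any(levels <= 0 | levels >= 100)) {
    stop("levels must lie strictly between 0 and 100")
  }
  mk <- function(mat) {
    if (is.null(mat)) return(NULL)
    cbind(data.frame(t = as.integer(colnames(mat))), quantile_cols(mat, levels))
  }
  structure(list(beta = mk(draws$beta), alpha = mk(draws$alpha),
                 w = mk(draws$w),
                 sigma = apply(draws$sigma, 2, stats::median),
                 levels = levels, grid = draws$grid, method = draws$method),
            class = "posterior_summary")
}

#' Start-time estimate container
#'
#' @param start_min Minutes after stimulus onset, or `Inf`.
#' @param threshold_used `"99"`, `"95"`, `"90"` or `"none"`.
#' @param method `"bayes"`, `"kalman"` or `"heuristic"`.
#' @return An object of class `start_time_estimate`.
#' @export
start_time_estimate <- function(start_min, threshold_used, method) {
  if (is.finite(start_min) && start_min < 1) {
    stop("finite start_min must be >= 1 minute after onset")
  }
  if (is.infinite(start_min) != (threshold_used == "none")) {
    stop("threshold_used must be 'none' iff start_min is infinite")
  }
  structure(list(start_min = start_min, threshold_used = threshold_used,
                 method = method),
            class = "start_time_estimate")
}

#' @export
print.start_time_estimate <- function(x, ...) {
  cat(sprintf("<start_time_estimate> %s min after onset (method %s, threshold %s)\n",
              format(x$start_min), x$method, x$threshold_used))
  invisible(x)
}

#' Movement start time from interval upper bounds
#'
#' The start time is the first beam-period time point at which the 99%
#' upper bound of the stimulus coefficient is strictly negative; if that
#' never happens the threshold is lowered to 95%, then 90%; if still never,
#' the start time is infinite. A start at the onset index itself maps to 1
#' minute after onset.
#'
#' For an escape response the coefficient is positive, so the mirrored rule
#' applies: the first time the lower bound is strictly positive
#' (`direction = "escape"`).
#'
#' @param summary A `posterior_summary` whose `beta` table carries bounds at
#'   the 90, 95 and 99% levels (any subset is scanned, highest first).
#' @param grid A [time_grid()].
#' @param direction `"approach"` (default) or `"escape"`.
#' @return A [start_time_estimate()].
#' @export
estimate_start_from_intervals <- function(summary, grid,
                                          direction = c("approach", "escape")) {
  stopifnot(inherits(summary, "posterior_summary"), inherits(grid, "time_grid"))
  direction <- match.arg(direction)
  beta <- summary$beta
  for (L in sort(summary$levels, decreasing = TRUE)) {
    up <- if (direction == "approach") beta[[paste0("upper", L)]] else
      -beta[[paste0("lower", L)]]
    hit <- which(up < 0)
    if (length(hit)) {
      t_star <- beta$t[hit[1L]]
      return(start_time_estimate(start_min_from_index(t_star, grid),
                                 as.character(L), summary$method))
    }
  }
  start_time_estimate(Inf, "none", summary$method)
}

#' Reconstruct the distance trajectory from posterior velocity states
#'
#' Per draw, `distance[t] = d0 + sum_{i <= t} alpha[i]`; the band is the
#' equal-tailed credible interval of those cumulative sums. Frame 0 is `d0`
#' exactly.
#'
#' @param draws A `posterior_draws`.
#' @param d0 Initial distance (um).
#' @param levels Interval levels, default 99.
#' @return Data frame with `frame` (0..T), `median` and bounds per level.
#' @export
reconstruct_distance <- function(draws, d0, levels = 99) {
  stopifnot(inherits(draws, "posterior_draws"))
  dist <- d0 + t(apply(draws$alpha, 1, cumsum))
  if (nrow(draws$alpha) == 1L) dist <- matrix(dist, nrow = 1)
  colnames(dist) <- seq_len(ncol(dist))
  out <- cbind(data.frame(frame = c(0L, seq_len(ncol(dist)))),
               rbind(rep(d0, 1 + 2 * length(levels)),
                     as.matrix(quantile_cols(dist, levels))))
  names(out)[2] <- "median"
  rownames(out) <- NULL
  out
}
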