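#' Map detected start times to common-model offsets
#'
#' The common model assumes an imaginary organelle at distance zero whose
#' coefficient trajectory every real organelle joins after its own lag. An
#' organelle whose movement begins at absolute velocity index `t*` (i.e.
#' `start_min = t* - (onset - 1)` minutes after onset) enters the common
#' trajectory at its own start, which under the model's indexing means an
#' integer offset `start[n] = start_min + 1`: an immediate responder
#' (`start_min = 1`) has offset 2 and simply follows the common coefficient
#' with no shift. Offsets below 2 (movement before onset) are rejected, as
#' are infinite start times (such organelles are excluded upstream).
#'
#' @param starts_min Per-organelle start times in minutes after onset
#'   (finite).
#' @param grid A [time_grid()].
#' @return Integer vector of offsets `start[n] >= 2`.
#' @export
map_start_offsets <- function(starts_min, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (any(!is.finite(starts_min))) {
    stop("infinite start times must be excluded before the common model")
  }
  offs <- as.integer(round(starts_min / grid$frame_interval)) + 1L
  if (any(offs < 2L)) {
    stop("start offset < 2: movement before stimulus onset is inconsistent ",
         "with the common model")
  }
  offs
}

#' Fit the per-cell common-dynamics model
#'
#' Hierarchical state-space model for one cell: a single white-noise series
#' `w[t]` shared by all organelles, a common stimulus-coefficient random
#' walk `beta_common[t]` over the beam period, and each organelle `n`
#' observing `y[t,n] ~ N(w[t] + beta_each[t,n], sigma_y^2)` where
#' `beta_each[t,n]` is zero until the organelle's own start and equals the
#' common trajectory shifted to begin there afterwards. Posterior sampling
#' uses the same Gibbs machinery as [fit_individual()]; with a single
#' organelle whose offset is 2 the model reduces exactly to the individual
#' model.
#'
#' @param Y Velocity matrix, `grid$T` rows by N organelle columns.
#' @param start_offsets Integer offsets from [map_start_offsets()].
#' @param spec An [individual_model_spec()] (priors and grid).
#' @param mcmc An [mcmc_config()].
#' @return An object of class `posterior_draws` with `method = "common"`;
#'   `beta` holds the common coefficient and `alpha` the common velocity
#'   `w[t] + beta_common[t] * beam[t]`.
#' @export
fit_common <- function(Y, start_offsets, spec, mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "individual_model_spec"))
  grid <- spec$grid
  Y <- as.matrix(Y)
  if (nrow(Y) != grid$T) stop("Y must have grid$T rows")
  start_offsets <- as.integer(start_offsets)
  if (length(start_offsets) != ncol(Y)) {
    stop("one start offset per organelle column is required")
  }
  if (any(start_offsets < 2L)) stop("start offsets must be >= 2")
  # organelle n's coefficient begins at absolute index onset + offset - 2
  t_first <- grid$onset + start_offsets - 2L
  drop <- t_first > grid$T
  if (any(drop)) {
    warning(sum(drop), " organelle(s) start after the series end; dropped")
    Y <- Y[, !drop, drop = FALSE]
    t_first <- t_first[!drop]
    if (!ncol(Y)) stop("no organelle starts within the observed series")
  }
  fit <- fit_lgssm_mcmc(Y, t_first = t_first, grid = grid,
                        prior_sd_scale = spec$prior_sd_scale,
                        fix = spec$fix, mcmc = mcmc)
  beta <- fit$beta
  colnames(beta) <- grid$onset:grid$T
  # common alpha: the imaginary organelle at distance zero responds with no
  # lag, i.e. beta_common enters at onset
  alpha <- alpha_from_draws(beta, fit$w, grid$onset, grid)
  if (!is.null(fit$w)) colnames(fit$w) <- seq_len(grid$T)
  structure(list(beta = beta, alpha = alpha, w = fit$w, sigma = fit$sigma,
                 chain_id = fit$chain_id, rhat = fit$rhat,
                 converged = fit$converged, grid = grid, method = "common",
                 start_offsets = start_offsets, n_organelles = ncol(Y)),
            class = "posterior_draws")
}

#' Reconstruct the common distance trajectory
#'
#' Per posterior draw, `dist_common[t] = sum_{i<=t} alpha_common[i] -
#' sum_{i<=onset-1} alpha_common[i]`, anchoring the trajectory to zero at
#' the last pre-stimulus step; the anchor holds exactly for every draw.
#'
#' @param draws A `posterior_draws` from [fit_common()].
#' @param levels Interval levels, default 95.
#' @return Data frame with `t` (1..T), `median` and bounds per level.
#' @export
reconstruct_common_distance <- function(draws, levels = 95) {
  stopifnot(inherits(draws, "posterior_draws"))
  g <- draws$grid
  cs <- t(apply(draws$alpha, 1, cumsum))
  if (nrow(draws$alpha) == 1L) cs <- matrix(cs, nrow = 1)
  anchor <- if (g$onset > 1L) cs[, g$onset - 1L] else 0
  dist <- cs - anchor
  colnames(dist) <- seq_len(ncol(dist))
  out <- cbind(data.frame(t = seq_len(ncol(dist))), quantile_cols(dist, levels))
  rownames(out) <- NULL
  out
}
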