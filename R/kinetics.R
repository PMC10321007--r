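#' Per-organelle summaries of the fitted dynamics
#'
#' Collapses a beam-period posterior into the per-organelle quantities used
#' by the downstream regressions: the mean and the most negative value of
#' the per-time coefficient medians, the coefficient's posterior SD across
#' time (median over draws of each draw's across-time SD, when draws are
#' available; the SD of the medians otherwise), the analogous velocity
#' summaries from the `alpha` medians, the distance at the start of
#' irradiation (`distances[onset - 1]`, the last pre-stimulus frame), and
#' the chosen detector's start time.
#'
#' @param summary A `posterior_summary` (Bayesian or Kalman route).
#' @param detector_start A [start_time_estimate()].
#' @param track The [cell_track()] the fit was run on.
#' @param grid A [time_grid()].
#' @param draws Optional `posterior_draws` for the across-time SD; NULL
#'   falls back to the SD of the medians.
#' @return An object of class `track_summary` (also a one-row data frame
#'   friendly list): `mean_coef`, `min_coef`, `sd_coef`, `mean_vel`,
#'   `min_vel`, `d_start`, `start_min`, `start_finite`, ids.
#' @export
track_summaries <- function(summary, detector_start, track, grid,
                            draws = NULL) {
  stopifnot(inherits(summary, "posterior_summary"),
            inherits(detector_start, "start_time_estimate"),
            inherits(track, "cell_track"), inherits(grid, "time_grid"))
  beta_med <- summary$beta$median
  if (any(!is.finite(beta_med))) stop("non-finite posterior medians")
  beam_t <- summary$beta$t
  alpha_med <- summary$alpha$median[summary$alpha$t %in% beam_t]
  sd_coef <- if (!is.null(draws)) {
    stats::median(apply(draws$beta, 1, stats::sd))
  } else {
    stats::sd(beta_med)
  }
  structure(list(
    cell_id = track$cell_id, organelle_id = track$organelle_id,
    mean_coef = mean(beta_med), min_coef = min(beta_med), sd_coef = sd_coef,
    mean_vel = mean(alpha_med), min_vel = min(alpha_med),
    d_start = distance_at_onset(track$distances, grid),
    start_min = detector_start$start_min,
    start_finite = is.finite(detector_start$start_min),
    method = detector_start$method),
    class = "track_summary")
}

#' @export
as.data.frame.track_summary <- function(x, ...) {
  data.frame(cell = x$cell_id, organelle = x$organelle_id,
             mean_coef = x$mean_coef, min_coef = x$min_coef,
             sd_coef = x$sd_coef, mean_vel = x$mean_vel, min_vel = x$min_vel,
             d_start = x$d_start, start_min = x$start_min,
             method = x$method, stringsAsFactors = FALSE)
}

#' Signal-transfer speed of a cell by robust regression
#'
#' Repeated-median regression of the distance from the stimulus at the
#' start of irradiation (response, um) on the movement start time
#' (explanatory, min): the slope is the cell's signal-transfer speed in
#' um/min. Organelles with infinite start times are excluded; fewer than 3
#' finite starts raise an error (callers typically skip such cells with a
#' notice).
#'
#' @param starts Per-organelle start times, minutes after onset (may
#'   contain `Inf`).
#' @param d_start Per-organelle distances at irradiation start (um).
#' @param cell_id Optional label carried through to the result.
#' @param n_boot,seed Passed to [repeated_median_fit()].
#' @return A `regression_fit` with extra fields `cell_id` and `speed`
#'   (= slope, um/min).
#' @export
fit_signal_speed <- function(starts, d_start, cell_id = NA_character_,
                             n_boot = 2000L, seed = 1L) {
  keep <- is.finite(starts) & is.finite(d_start)
  if (sum(keep) < 3L) {
    stop(sprintf("cell %s: need >= 3 organelles with finite start times (have %d)",
                 cell_id, sum(keep)))
  }
  fit <- repeated_median_fit(starts[keep], d_start[keep],
                             n_boot = n_boot, seed = seed)
  fit$cell_id <- cell_id
  fit$speed <- fit$slope
  fit
}

#' Signal transfer time from distance and speed
#'
#' Minutes for the intracellular signal to travel from the stimulus edge to
#' the organelle: `d_start / speed`.
#'
#' @param d_start Distance at irradiation start (um); vectorised.
#' @param speed Signal-transfer speed (um/min), must be positive.
#' @return Transfer time(s) in minutes.
#' @examples
#' signal_transfer_time(7.7, 0.77)  # 10
#' @export
signal_transfer_time <- function(d_start, speed) {
  if (!is.finite(speed) || speed <= 0) stop("speed must be positive")
  d_start / speed
}

#' Compare signal transfer time with total reaction time
#'
#' One-sided exact Wilcoxon signed-rank test of transfer time < total
#' reaction time (alternative "less") on paired per-organelle values,
#' testing whether warm-up periods (total minus transfer) are detectable.
#'
#' @param transfer Per-organelle signal transfer times (min).
#' @param total Per-organelle total reaction (start) times (min).
#' @return The [wilcoxon_signed_rank()] result; `degenerate = TRUE` when
#'   every difference is zero.
#' @export
compare_transfer_vs_total <- function(transfer, total) {
  keep <- is.finite(transfer) & is.finite(total)
  if (!any(keep)) stop("no finite pairs")
  wilcoxon_signed_rank(transfer[keep], total[keep], alternative = "less")
}
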