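#' Default stimulus-coefficient pulse
#'
#' Returns a function giving the drift coefficient (um/min) as a function of
#' minutes since the organelle's own movement start: a linear ramp to
#' `-depth` over `ramp` minutes, a plateau, then linear recovery to zero
#' starting `plateau_end` minutes after the start. Negative values drive the
#' organelle toward the stimulus (accumulation); pass `depth < 0` for an
#' escape-style positive pulse.
#'
#' @param depth Pulse depth in um/min (default 0.5; positive number gives a
#'   negative, accumulation-type coefficient).
#' @param ramp Ramp-in duration, minutes (default 5).
#' @param plateau_end Minutes after start at which recovery begins (default 40).
#' @param recovery Recovery duration, minutes (default 20).
#' @return A vectorised function `f(s)` of minutes-since-start `s >= 0`.
#' @export
pulse_profile <- function(depth = 0.5, ramp = 5, plateau_end = 40, recovery = 20) {
  force(depth); force(ramp); force(plateau_end); force(recovery)
  function(s) {
    mag <- ifelse(s < plateau_end,
                  pmin((s + 1) / ramp, 1),
                  pmax(0, 1 - (s - plateau_end) / recovery))
    -depth * mag
  }
}

#' Simulation parameters
#'
#' Bundles everything the trajectory generator needs. The generative model
#' mirrors the analysis model: per velocity step, `y[t] = alpha[t] + e[t]`
#' with observation noise `e ~ N(0, sigma_y^2)`; `alpha[t] = w[t]` before
#' the organelle's own start and `alpha[t] = w[t] + beta(t - start)` after,
#' with random-walk-driving white noise `w ~ N(0, sigma_w^2)`. Each
#' organelle's start lags the stimulus onset by
#' `round(d0 / signal_speed) + warmup_min` minutes, emulating an
#' intracellular signal travelling at `signal_speed` from the stimulus edge.
#'
#' @param grid A [time_grid()].
#' @param n_cells Number of cells (default 1).
#' @param organelles_per_cell Organelles per cell (default 10).
#' @param initial_distances Either a length-2 range (um) to sample uniformly,
#'   or an explicit vector recycled per cell. Default `c(5, 25)`.
#' @param sigma_w Random-walk velocity SD, um/min (default 0.3).
#' @param sigma_y Observation SD, um/min (default 0.3).
#' @param signal_speed True signal-transfer speed, um/min (default 0.8).
#' @param warmup_min Extra minutes added to every lag (default 0).
#' @param beta_profile Function of minutes-since-start giving the stimulus
#'   coefficient (default [pulse_profile()]).
#' @param with_xy Place organelles on rays from a beam centre so the optional
#'   coordinates are consistent with the distances (default FALSE).
#' @param seed Integer seed; the run is fully reproducible given it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(grid = time_grid(), n_cells = 1L,
                       organelles_per_cell = 10L,
                       initial_distances = c(5, 25),
                       sigma_w = 0.3, sigma_y = 0.3,
                       signal_speed = 0.8, warmup_min = 0,
                       beta_profile = pulse_profile(),
                       with_xy = FALSE, seed = 1L) {
  stopifnot(inherits(grid, "time_grid"))
  if (sigma_w < 0 || sigma_y < 0) stop("noise SDs must be >= 0")
  if (signal_speed <= 0) stop("signal_speed must be > 0")
  if (!is.function(beta_profile)) stop("beta_profile must be a function")
  structure(
    list(grid = grid, n_cells = as.integer(n_cells),
         organelles_per_cell = as.integer(organelles_per_cell),
         initial_distances = as.numeric(initial_distances),
         sigma_w = sigma_w, sigma_y = sigma_y,
         signal_speed = signal_speed, warmup_min = warmup_min,
         beta_profile = beta_profile, with_xy = isTRUE(with_xy),
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Deterministic per-organelle substream seed so adding organelles never
# perturbs earlier ones. Kept below 2^31.
substream_seed <- function(seed, idx) {
  (as.double(seed) * 48271 + idx * 69621) %% 2147483647
}

sim_one_organelle <- function(params, d0, org_seed) {
  g <- params$grid
  T_ <- g$T
  lag <- as.integer(round(d0 / params$signal_speed) + round(params$warmup_min))
  t_first <- g$onset + lag                      # first stimulus-affected velocity index
  set.seed(org_seed)
  w <- stats::rnorm(T_, 0, params$sigma_w)
  eps <- stats::rnorm(T_, 0, params$sigma_y)
  beta_each <- numeric(T_)
  if (t_first <= T_) {
    idx <- t_first:T_
    beta_each[idx] <- params$beta_profile((idx - t_first) * g$frame_interval)
  }
  alpha <- w + beta_each
  y <- alpha + eps
  d <- d0 + cumsum(y)
  floored <- d < 0
  d[floored] <- 0
  list(distances = c(d0, d), true_start_min = lag, true_beta = beta_each,
       true_alpha = alpha, n_floored = sum(floored))
}

sim_trackset <- function(params) {
  g <- params$grid
  tracks <- list()
  truth_rows <- list()
  truth_beta <- list()
  beam_centre <- c(0, 0)
  n_floored_total <- 0L
  idx <- 0L
  for (ci in seq_len(params$n_cells)) {
    cid <- sprintf("cell%02d", ci)
    for (oi in seq_len(params$organelles_per_cell)) {
      idx <- idx + 1L
      oid <- sprintf("org%02d", oi)
      s_d0 <- substream_seed(params$seed, 2L * idx)
      s_tr <- substream_seed(params$seed, 2L * idx + 1L)
      ini <- params$initial_distances
      if (length(ini) == 2L) {  # a length-2 vector is a uniform range
        set.seed(s_d0)
        d0 <- stats::runif(1, min(ini), max(ini))
      } else {
        d0 <- ini[((oi - 1L) %% length(ini)) + 1L]
      }
      sim <- sim_one_organelle(params, d0, s_tr)
      n_floored_total <- n_floored_total + sim$n_floored
      xy <- NULL
      if (params$with_xy) {
        # place the organelle on a fixed ray from the beam centre; radial
        # coordinate follows the distance series (beam edge at the centre,
        # i.e. zero beam radius, keeps distance == euclidean norm)
        set.seed(s_d0 + 1)
        theta <- stats::runif(1, 0, 2 * pi)
        xy <- cbind(beam_centre[1] + sim$distances * cos(theta),
                    beam_centre[2] + sim$distances * sin(theta))
      }
      tracks[[idx]] <- cell_track(cid, oid, sim$distances, g, xy = xy)
      truth_rows[[idx]] <- data.frame(
        cell = cid, organelle = oid, d0 = d0,
        true_start_min = sim$true_start_min,
        signal_speed = params$signal_speed, stringsAsFactors = FALSE)
      truth_beta[[idx]] <- sim$true_beta
    }
  }
  if (n_floored_total > 0.5 * g$n_frames * idx) {
    warning("beta profile drove distances below 0 for a majority of frames; ",
            "distances were floored at 0")
  }
  geom <- if (params$with_xy) {
    list(centre = beam_centre, radius = 0, organelle_radius = 1)
  } else NULL
  list(
    tracks = track_set(g, tracks, beam_geometry = geom),
    truth = structure(
      list(per_organelle = do.call(rbind, truth_rows),
           true_beta = truth_beta, signal_speed = params$signal_speed),
      class = "sim_truth")
  )
}

#' Simulate an accumulation response
#'
#' Generates tracked trajectories with the statistical structure the
#' analysis models assume: pre-stimulus random walk, stimulus-induced drift
#' beginning after a distance-dependent lag (`round(d0/signal_speed) +
#' warmup`), and Gaussian observation error. Distances are floored at zero
#' (an organelle cannot be nearer than the stimulus edge); a warning is
#' raised if flooring affects a majority of frames.
#'
#' @param params A [sim_params()].
#' @return List with `tracks` (a [track_set()]) and `truth` (a `sim_truth`
#'   with per-organelle `true_start_min`, true coefficient trajectories and
#'   the true signal speed).
#' @examples
#' sim <- simulate_accumulation(sim_params(n_cells = 1, organelles_per_cell = 3,
#'                                         seed = 7))
#' sim$truth$per_organelle
#' @export
simulate_accumulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sim_trackset(params)
}

#' Simulate an escape response
#'
#' Like [simulate_accumulation()] but with a positive drift coefficient
#' (distance from the stimulus increases), emulating a microbe swimming away
#' from localised heating: by default a 200-min series in which the stimulus
#' is ON for the final 70 velocity steps (distance frames 0..199, heating
#' during minutes 130..199).
#'
#' @param params A [sim_params()]; if its grid is the default 120-frame grid
#'   it is replaced by the 200-frame escape grid, and if its profile is the
#'   default accumulation pulse it is flipped to a positive escape pulse.
#' @return As [simulate_accumulation()].
#' @export
simulate_escape <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (identical(unclass(params$grid), unclass(time_grid()))) {
    # 200 distance frames (0..199 min); heating ON for velocity steps 130..199
    params$grid <- time_grid(n_frames = 200L, onset = 130L)
  }
  test_prof <- params$beta_profile(c(0, 10))
  if (all(test_prof <= 0)) {
    # default escape profile: a transient 30-min dash away from the heat
    # (ramp 5, plateau to 20 min, recovery over 10), so the series contains
    # both the response and the post-response plateau; an accumulation-style
    # 60-min episode would fill the whole terminal stimulus window
    depth <- -min(params$beta_profile(0:60))
    params$beta_profile <- pulse_profile(depth = -depth, ramp = 5,
                                         plateau_end = 20, recovery = 10)
  }
  sim_trackset(params)
}

#' Write simulation ground truth to CSV
#'
#' @param truth A `sim_truth` from the simulators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  utils::write.csv(truth$per_organelle, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
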