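#' Observation time grid for tracked trajectories
#'
#' Defines the shared sampling grid of a tracked experiment: distance frames
#' are indexed `0..T` (so `n_frames = T + 1` observations per track) and
#' velocity steps are indexed `1..T`, where velocity index `t` is the step
#' ending at distance frame `t`. The stimulus (e.g. a blue microbeam) is OFF
#' for velocity indices `1..onset-1` and ON for `onset..T`.
#'
#' The defaults describe a 120-min recording at 1-min intervals with the
#' stimulus switched on at the 30th velocity step, i.e. 29 pre-stimulus
#' velocity points and 90 stimulus points.
#'
#' @param n_frames Number of distance frames (default 120).
#' @param frame_interval Minutes between frames (default 1).
#' @param onset First velocity index with the stimulus ON (default 30).
#' @return An object of class `time_grid` with fields `n_frames`,
#'   `frame_interval`, `onset`, and `T` (last velocity index).
#' @examples
#' g <- time_grid()
#' g$T            # 119
#' sum(beam_indicator(g))  # 90 stimulus minutes
#' @export
time_grid <- function(n_frames = 120L, frame_interval = 1, onset = 30L) {
  n_frames <- as.integer(n_frames)
  onset <- as.integer(onset)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  T_ <- n_frames - 1L
  if (onset < 1L || onset > T_) {
    stop("onset must lie in 1..", T_, " (velocity indices)")
  }
  structure(
    list(n_frames = n_frames, frame_interval = frame_interval,
         onset = onset, T = T_),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d frames (0..%d), interval %g min, stimulus ON at velocity index %d..%d\n",
    x$n_frames, x$T, x$frame_interval, x$onset, x$T))
  invisible(x)
}

#' Stimulus on/off indicator over velocity indices
#'
#' Returns the 0/1 stimulus indicator for velocity indices `1..T`: 0 before
#' the onset index, 1 from onset onwards.
#'
#' @param grid A [time_grid()].
#' @return Integer vector of length `grid$T`.
#' @export
beam_indicator <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  as.integer(seq_len(grid$T) >= grid$onset)
}

# Internal index helpers: distance frame f (0..T) lives at R index f + 1.
frame_index <- function(f) f + 1L

# Distance at the start of irradiation = last pre-stimulus frame (onset - 1).
distance_at_onset <- function(distances, grid) {
  distances[frame_index(grid$onset - 1L)]
}

# Convert an absolute velocity index t* to minutes after stimulus onset
# (immediate response, t* = onset, maps to 1 min).
start_min_from_index <- function(t_star, grid) {
  (t_star - (grid$onset - 1L)) * grid$frame_interval
}
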