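#' Single tracked organelle
#'
#' A `cell_track` holds one organelle's distance-from-stimulus time series on
#' a [time_grid()]: the distance (um) between the organelle centre and the
#' stimulus edge at every frame, plus optional 2-D centre coordinates and an
#' optional visually annotated start time.
#'
#' @param cell_id,organelle_id Labels identifying the track.
#' @param distances Numeric vector of distances (um), one per frame, finite
#'   and non-negative.
#' @param grid A [time_grid()] the distances live on.
#' @param xy Optional numeric matrix (`n_frames` x 2) of centre coordinates (um).
#' @param visual_start Optional visually estimated start time in minutes
#'   after stimulus onset.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(cell_id, organelle_id, distances, grid,
                       xy = NULL, visual_start = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  distances <- as.numeric(distances)
  if (length(distances) != grid$n_frames) {
    stop(sprintf("track %s/%s: %d distances but grid has %d frames",
                 cell_id, organelle_id, length(distances), grid$n_frames))
  }
  if (any(!is.finite(distances))) {
    bad <- which(!is.finite(distances))[1L] - 1L
    stop(sprintf("track %s/%s: non-finite distance at frame %d",
                 cell_id, organelle_id, bad))
  }
  if (any(distances < 0)) {
    bad <- which(distances < 0)[1L] - 1L
    stop(sprintf("track %s/%s: negative distance at frame %d",
                 cell_id, organelle_id, bad))
  }
  if (!is.null(xy)) {
    xy <- as.matrix(xy)
    if (nrow(xy) != grid$n_frames || ncol(xy) != 2L) {
      stop(sprintf("track %s/%s: xy must be %d x 2", cell_id, organelle_id,
                   grid$n_frames))
    }
  }
  structure(
    list(cell_id = as.character(cell_id),
         organelle_id = as.character(organelle_id),
         distances = distances, xy = xy,
         visual_start = if (is.null(visual_start)) NULL else as.numeric(visual_start)),
    class = "cell_track"
  )
}

#' Collection of tracks sharing one time grid
#'
#' @param grid A [time_grid()].
#' @param tracks List of [cell_track()] objects; `(cell_id, organelle_id)`
#'   pairs must be unique.
#' @param beam_geometry Optional list with `centre` (length-2 um), `radius`
#'   (um) and `organelle_radius` (um), used by the pairwise alignment
#'   judgement.
#' @return An object of class `track_set`.
#' @export
track_set <- function(grid, tracks, beam_geometry = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  if (!length(tracks)) stop("track_set needs at least one track")
  ok <- vapply(tracks, inherits, logical(1), "cell_track")
  if (!all(ok)) stop("all elements of `tracks` must be cell_track objects")
  ids <- vapply(tracks, function(tr) paste(tr$cell_id, tr$organelle_id, sep = "\r"),
                character(1))
  if (anyDuplicated(ids)) {
    d <- tracks[[which(duplicated(ids))[1L]]]
    stop(sprintf("duplicate (cell, organelle) pair: (%s, %s)",
                 d$cell_id, d$organelle_id))
  }
  for (tr in tracks) {
    if (length(tr$distances) != grid$n_frames)
      stop(sprintf("track %s/%s does not match the shared grid",
                   tr$cell_id, tr$organelle_id))
  }
  structure(list(grid = grid, tracks = tracks, beam_geometry = beam_geometry),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cells <- unique(vapply(x$tracks, `[[`, character(1), "cell_id"))
  cat(sprintf("<track_set> %d tracks in %d cell(s), %d frames each\n",
              length(x$tracks), length(cells), x$grid$n_frames))
  invisible(x)
}

#' Read tracked trajectories from CSV
#'
#' The CSV must hold columns `cell`, `organelle`, `time_min`, `distance_um`
#' and optionally `x_um`, `y_um`, `visual_start_min`, with exactly one row
#' per frame of `grid` for every `(cell, organelle)` pair. Frames may appear
#' in any order; they are sorted by `time_min`. Missing frames, duplicated
#' frames, or non-numeric distances are rejected with a message naming the
#' offending cell, organelle and time.
#'
#' @param path Path to a CSV file.
#' @param grid A [time_grid()] describing the expected frames.
#' @return A [track_set()].
#' @seealso [write_tracks()] for the inverse operation.
#' @export
load_tracks <- function(path, grid) {
  stopifnot(inherits(grid, "time_grid"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell = "character", organelle = "character"))
  need <- c("cell", "organelle", "time_min", "distance_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  has_xy <- all(c("x_um", "y_um") %in% names(df))
  has_vis <- "visual_start_min" %in% names(df)

  expected <- (seq_len(grid$n_frames) - 1L) * grid$frame_interval
  key <- paste(df$cell, df$organelle, sep = "\r")
  tracks <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    cid <- sub$cell[1L]; oid <- sub$organelle[1L]
    dup <- sub$time_min[duplicated(sub$time_min)]
    if (length(dup)) {
      stop(sprintf("duplicate row for cell %s, organelle %s at time %g",
                   cid, oid, dup[1L]))
    }
    missing_t <- setdiff(expected, sub$time_min)
    if (length(missing_t)) {
      stop(sprintf("missing frame for cell %s, organelle %s at time %g",
                   cid, oid, missing_t[1L]))
    }
    extra_t <- setdiff(sub$time_min, expected)
    if (length(extra_t)) {
      stop(sprintf("unexpected frame for cell %s, organelle %s at time %g",
                   cid, oid, extra_t[1L]))
    }
    sub <- sub[order(sub$time_min), , drop = FALSE]
    d <- suppressWarnings(as.numeric(sub$distance_um))
    if (any(is.na(d))) {
      bad <- sub$time_min[which(is.na(d))[1L]]
      stop(sprintf("non-numeric distance for cell %s, organelle %s at time %g",
                   cid, oid, bad))
    }
    xy <- NULL
    if (has_xy) {
      xy <- cbind(as.numeric(sub$x_um), as.numeric(sub$y_um))
      if (any(is.na(xy))) xy <- NULL
    }
    vis <- NULL
    if (has_vis) {
      v <- suppressWarnings(as.numeric(sub$visual_start_min[1L]))
      if (is.finite(v)) vis <- v
    }
    tracks[[length(tracks) + 1L]] <-
      cell_track(cid, oid, d, grid, xy = xy, visual_start = vis)
  }
  track_set(grid, tracks)
}

#' Write a track set to CSV
#'
#' Emits the same schema [load_tracks()] reads, so a write/load round trip
#' preserves all values.
#'
#' @param tracks A [track_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  g <- tracks$grid
  tmin <- (seq_len(g$n_frames) - 1L) * g$frame_interval
  has_xy <- any(vapply(tracks$tracks, function(tr) !is.null(tr$xy), logical(1)))
  has_vis <- any(vapply(tracks$tracks, function(tr) !is.null(tr$visual_start), logical(1)))
  rows <- lapply(tracks$tracks, function(tr) {
    out <- data.frame(cell = tr$cell_id, organelle = tr$organelle_id,
                      time_min = tmin, distance_um = tr$distances,
                      stringsAsFactors = FALSE)
    if (has_xy) {
      if (is.null(tr$xy)) { out$x_um <- NA_real_; out$y_um <- NA_real_ }
      else { out$x_um <- tr$xy[, 1L]; out$y_um <- tr$xy[, 2L] }
    }
    if (has_vis) {
      out$visual_start_min <- if (is.null(tr$visual_start)) NA_real_ else tr$visual_start
    }
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' First-difference velocity of a track
#'
#' Velocity at index `t` is `distances[t] - distances[t-1]` (um/min for a
#' 1-min grid): negative values mean the organelle approached the stimulus.
#' The cumulative sum of the velocities plus the initial distance reproduces
#' the distance series exactly.
#'
#' @param track A [cell_track()].
#' @param grid A [time_grid()].
#' @return An object of class `velocity_series`: list with `y` (length
#'   `grid$T`), `beam` (stimulus indicator per [beam_indicator()]), `d0`
#'   (initial distance) and `grid`.
#' @export
compute_velocity <- function(track, grid) {
  stopifnot(inherits(track, "cell_track"), inherits(grid, "time_grid"))
  if (length(track$distances) != grid$n_frames)
    stop("track does not match grid")
  structure(
    list(y = diff(track$distances), beam = beam_indicator(grid),
         d0 = track$distances[1L], grid = grid),
    class = "velocity_series"
  )
}

#' Build a velocity series directly from a numeric vector
#'
#' Convenience constructor used by the model-fitting functions when the
#' velocities come from somewhere other than a stored track.
#'
#' @param y Numeric velocity vector of length `grid$T`.
#' @param grid A [time_grid()].
#' @param d0 Initial distance (um), default 0.
#' @return A `velocity_series`.
#' @export
velocity_series <- function(y, grid, d0 = 0) {
  stopifnot(inherits(grid, "time_grid"))
  y <- as.numeric(y)
  if (length(y) != grid$T) stop("y must have length grid$T = ", grid$T)
  if (any(!is.finite(y))) stop("velocities must be finite")
  structure(list(y = y, beam = beam_indicator(grid), d0 = as.numeric(d0),
                 grid = grid),
            class = "velocity_series")
}
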