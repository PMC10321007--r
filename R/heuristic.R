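#' Parameters of the model-free start-time detector
#'
#' @param k_consec Consecutive strictly decreasing steps required (default 3).
#' @param ma_window Trailing moving-average window, frames (default 9, one
#'   tenth of the default 90-min stimulus period).
#' @param horizon Forward look-ahead for the strong-decrease criterion,
#'   frames (default 13).
#' @param fold Multiplier on the mean forward decrease (default 1.5).
#' @return An object of class `heuristic_params`.
#' @export
heuristic_params <- function(k_consec = 3L, ma_window = 9L, horizon = 13L,
                             fold = 1.5) {
  k_consec <- as.integer(k_consec); ma_window <- as.integer(ma_window)
  horizon <- as.integer(horizon)
  if (k_consec < 1L || ma_window < 1L || horizon < 1L || fold <= 0) {
    stop("all heuristic parameters must be positive")
  }
  structure(list(k_consec = k_consec, ma_window = ma_window,
                 horizon = horizon, fold = fold),
            class = "heuristic_params")
}

#' Model-free movement start detection on raw distances
#'
#' Scans the beam period for the first time point `t` meeting all three
#' criteria: (1) the distance decreased strictly at each of the last
#' `k_consec` steps ending at `t`; (2) the trailing mean of the one-step
#' distance changes over `ma_window` steps ending at `t` is negative
#' (long-term approach); (3) the decrease over the next `horizon` frames,
#' `D(t) = d[t] - d[t + horizon]`, exceeds `fold` times the mean of `D(s)`
#' over all beam-period `s` where the look-ahead is defined (strong stimulus
#' influence). The criteria are scale- and translation-invariant in the
#' distances. If no `t` qualifies the start time is infinite.
#'
#' For an escape response (distance increasing away from the stimulus) set
#' `direction = "escape"`: the criteria are applied to the mirrored series
#' `max(d) - d`, an exact sign-symmetric reading of the same rules (all
#' three criteria are translation-invariant).
#'
#' @param track A [cell_track()].
#' @param grid A [time_grid()].
#' @param params A [heuristic_params()].
#' @param direction `"approach"` (accumulation, default) or `"escape"`.
#' @return A [start_time_estimate()] with `method = "heuristic"` (the
#'   threshold slot records `"criteria"` for a finite hit).
#' @export
detect_start_heuristic <- function(track, grid, params = heuristic_params(),
                                   direction = c("approach", "escape")) {
  stopifnot(inherits(track, "cell_track"), inherits(grid, "time_grid"),
            inherits(params, "heuristic_params"))
  direction <- match.arg(direction)
  d <- track$distances                    # frames 0..T at indices 1..T+1
  if (direction == "escape") d <- max(d) - d
  T_ <- grid$T; t0 <- grid$onset
  post_len <- T_ - t0 + 1L
  if (params$ma_window > post_len || params$horizon > post_len) {
    stop("ma_window and horizon must not exceed the post-onset length")
  }
  dd <- diff(d)                           # step ending at frame t, index t

  # forward decreases over the beam period, where defined
  s_valid <- t0:(T_ - params$horizon)
  if (!length(s_valid)) {
    return(start_time_estimate(Inf, "none", "heuristic"))
  }
  Dfun <- function(t) d[frame_index(t)] - d[frame_index(t + params$horizon)]
  mean_D <- mean(vapply(s_valid, Dfun, numeric(1)))

  for (t in t0:T_) {
    # criterion 1: k_consec strictly decreasing steps ending at t
    steps <- (t - params$k_consec + 1L):t
    if (steps[1L] < 1L) next
    if (!all(dd[steps] < 0)) next
    # criterion 2: trailing moving average of changes over ma_window
    lo <- t - params$ma_window + 1L
    if (lo < 1L) next
    if (mean(dd[lo:t]) >= 0) next
    # criterion 3: forward decrease vs fold x mean decrease
    if (t + params$horizon > T_) next     # undefined look-ahead cannot trigger
    if (!(Dfun(t) > params$fold * mean_D)) next
    return(start_time_estimate(start_min_from_index(t, grid), "criteria",
                               "heuristic"))
  }
  start_time_estimate(Inf, "none", "heuristic")
}

#' Tune the heuristic detector against visual annotations
#'
#' Exhaustively evaluates every combination of the supplied per-parameter
#' candidate lists and returns the combination minimising the RMSE between
#' detected and visually annotated start times. Tracks where either value
#' is infinite are dropped from that combination's RMSE (reducing n); a
#' combination that yields an infinite start on more than half of the
#' annotated tracks is disqualified. Ties are broken by the
#' lexicographically smallest `(k_consec, ma_window, horizon, fold)` tuple.
#'
#' @param tracks A [track_set()]; visual annotations are taken from each
#'   track's `visual_start` unless `visual` is supplied.
#' @param visual Optional named numeric vector of visual start times
#'   (minutes after onset), named `cell/organelle`.
#' @param grids Named list of candidate values for `k_consec`, `ma_window`,
#'   `horizon`, `fold`; missing entries default to the single default value.
#' @return List with `params` (the winning [heuristic_params()]), `rmse`
#'   (minutes), `n` (tracks used), and `table` (per-combination results).
#' @export
grid_search_params <- function(tracks, visual = NULL, grids = list()) {
  stopifnot(inherits(tracks, "track_set"))
  g <- tracks$grid
  if (is.null(visual)) {
    visual <- vapply(tracks$tracks, function(tr) {
      if (is.null(tr$visual_start)) NA_real_ else tr$visual_start
    }, numeric(1))
    names(visual) <- vapply(tracks$tracks, function(tr)
      paste(tr$cell_id, tr$organelle_id, sep = "/"), character(1))
  }
  keep <- is.finite(visual)
  if (!any(keep)) stop("no track has a finite visual start time")
  ids <- vapply(tracks$tracks, function(tr)
    paste(tr$cell_id, tr$organelle_id, sep = "/"), character(1))
  ann_tracks <- tracks$tracks[match(names(visual)[keep], ids)]
  vis <- visual[keep]

  defaults <- heuristic_params()
  cand <- list(
    k_consec = if (is.null(grids$k_consec)) defaults$k_consec else grids$k_consec,
    ma_window = if (is.null(grids$ma_window)) defaults$ma_window else grids$ma_window,
    horizon = if (is.null(grids$horizon)) defaults$horizon else grids$horizon,
    fold = if (is.null(grids$fold)) defaults$fold else grids$fold)
  if (any(!lengths(cand))) stop("empty candidate grid")
  combos <- expand.grid(fold = sort(cand$fold), horizon = sort(cand$horizon),
                        ma_window = sort(cand$ma_window),
                        k_consec = sort(cand$k_consec))
  # lexicographic order in (k_consec, ma_window, horizon, fold)
  combos <- combos[order(combos$k_consec, combos$ma_window, combos$horizon,
                         combos$fold), , drop = FALSE]

  res <- lapply(seq_len(nrow(combos)), function(i) {
    p <- heuristic_params(combos$k_consec[i], combos$ma_window[i],
                          combos$horizon[i], combos$fold[i])
    det <- vapply(ann_tracks, function(tr)
      detect_start_heuristic(tr, g, p)$start_min, numeric(1))
    inf_frac <- mean(!is.finite(det))
    both <- is.finite(det) & is.finite(vis)
    rmse <- if (inf_frac > 0.5 || !any(both)) Inf else
      sqrt(mean((det[both] - vis[both])^2))
    data.frame(k_consec = p$k_consec, ma_window = p$ma_window,
               horizon = p$horizon, fold = p$fold, rmse = rmse,
               n = sum(both), disqualified = inf_frac > 0.5)
  })
  tab <- do.call(rbind, res)
  best_i <- which.min(tab$rmse)   # first minimum == lexicographic tie-break
  if (!is.finite(tab$rmse[best_i])) {
    stop("every candidate combination was disqualified")
  }
  list(params = heuristic_params(tab$k_consec[best_i], tab$ma_window[best_i],
                                 tab$horizon[best_i], tab$fold[best_i]),
       rmse = tab$rmse[best_i], n = tab$n[best_i], table = tab)
}
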