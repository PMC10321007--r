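#' Pairwise signal-transfer speeds within a cell
#'
#' For every unordered pair of organelles with finite start times, the
#' nearer organelle at irradiation start is labelled `a` (ties in distance
#' broken by label order), and the pairwise speed is
#' `(d_b - d_a) / (start_b - start_a)` um/min. A negative speed means the
#' farther organelle responded earlier. Pairs with equal start times have
#' undefined speed and are excluded from sign counts. When 2-D positions at
#' onset and a beam geometry are available, each pair is judged aligned or
#' not via [judge_alignment()]; otherwise alignment is `NA`.
#'
#' @param summaries List of `track_summary` objects (or a data frame with
#'   columns `cell`, `organelle`, `d_start`, `start_min`) for one cell.
#' @param positions Optional matrix of onset positions (rows named by
#'   organelle, columns x/y, um).
#' @param beam_geometry Optional list with `centre` (x, y um) and
#'   `organelle_radius` (um).
#' @return Data frame with one row per pair: `organelle_a`, `organelle_b`,
#'   `delta_d`, `delta_start`, `speed`, `sign`, `aligned`.
#' @export
pairwise_speeds <- function(summaries, positions = NULL, beam_geometry = NULL) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, lapply(summaries, as.data.frame))
  df <- df[is.finite(df$start_min), , drop = FALSE]
  if (nrow(df) < 2L) stop("need >= 2 organelles with finite start times")
  n <- nrow(df)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- i; b <- j
    if (df$d_start[j] < df$d_start[i] ||
        (df$d_start[j] == df$d_start[i] &&
         df$organelle[j] < df$organelle[i])) { a <- j; b <- i }
    delta_d <- df$d_start[b] - df$d_start[a]
    delta_start <- df$start_min[b] - df$start_min[a]
    speed <- if (delta_start == 0) NA_real_ else delta_d / delta_start
    sgn <- if (is.na(speed)) NA_character_ else
      if (speed >= 0) "positive" else "negative"
    aligned <- NA
    if (!is.null(positions) && !is.null(beam_geometry) &&
        all(c(df$organelle[a], df$organelle[b]) %in% rownames(positions))) {
      aligned <- judge_alignment(
        near = positions[df$organelle[a], ],
        far = positions[df$organelle[b], ],
        beam_centre = beam_geometry$centre,
        organelle_radius = beam_geometry$organelle_radius)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      organelle_a = df$organelle[a], organelle_b = df$organelle[b],
      delta_d = delta_d, delta_start = delta_start, speed = speed,
      sign = sgn, aligned = aligned, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Geometric alignment judgement for an organelle pair
#'
#' A pair is "in a line" when the segment from the beam centre to the
#' farther organelle's centre passes through the nearer organelle: the
#' nearer centre's perpendicular distance to that segment is at most
#' `organelle_radius` and its projection falls within the segment.
#'
#' @param near,far Length-2 numeric centres (um) of the nearer and farther
#'   organelle at stimulus onset.
#' @param beam_centre Length-2 numeric centre of the stimulus (um).
#' @param organelle_radius Nominal organelle radius (um).
#' @return TRUE/FALSE, or NA if any coordinate is missing.
#' @export
judge_alignment <- function(near, far, beam_centre, organelle_radius) {
  near <- as.numeric(near); far <- as.numeric(far)
  beam_centre <- as.numeric(beam_centre)
  if (any(!is.finite(c(near, far, beam_centre)))) return(NA)
  v <- far - beam_centre
  len2 <- sum(v^2)
  if (len2 == 0) return(sqrt(sum((near - beam_centre)^2)) <= organelle_radius)
  u <- near - beam_centre
  tproj <- sum(u * v) / len2
  if (tproj < 0 || tproj > 1) return(FALSE)
  perp <- sqrt(max(0, sum(u^2) - tproj^2 * len2))
  perp <= organelle_radius
}

#' Alignment x slope-sign contingency analysis
#'
#' Cross-tabulates aligned vs not-aligned pairs against positive vs
#' negative pairwise speed and applies the exact two-sided Fisher test.
#' Pairs with unknown alignment or undefined speed are excluded.
#'
#' @param pairs Data frame from [pairwise_speeds()] (rows from several
#'   cells may be concatenated).
#' @return List with `table` (2x2: rows aligned/not_aligned, columns
#'   positive/negative) and `p_value`.
#' @export
alignment_contingency_fisher <- function(pairs) {
  keep <- !is.na(pairs$aligned) & !is.na(pairs$sign)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) stop("no pairs with both alignment and sign defined")
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("aligned", "not_aligned"),
                                c("positive", "negative")))
  tab["aligned", "positive"] <- sum(pairs$aligned & pairs$sign == "positive")
  tab["aligned", "negative"] <- sum(pairs$aligned & pairs$sign == "negative")
  tab["not_aligned", "positive"] <- sum(!pairs$aligned & pairs$sign == "positive")
  tab["not_aligned", "negative"] <- sum(!pairs$aligned & pairs$sign == "negative")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("contingency table has an empty margin")
  }
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p_value = ft$p_value)
}
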