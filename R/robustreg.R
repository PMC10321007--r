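#' Repeated-median (Siegel) robust line fit
#'
#' Slope = median over points i of the median over j != i of the pairwise
#' slopes `(y_j - y_i)/(x_j - x_i)` (pairs with equal x excluded);
#' intercept = median of `y_i - slope * x_i`. The estimator has a 50%
#' breakdown point. R^2 is computed as `1 - SS_res/SS_tot` on this fit and
#' can be negative for a poor robust fit, in which case the result is
#' flagged `degenerate`. The 95% CI for the slope and the two-sided p-value
#' for slope = 0 come from a seeded case-resampling bootstrap (percentile
#' interval; p from the bootstrap sign proportion).
#'
#' @param x,y Numeric vectors, `n >= 3`, at least 3 distinct x values.
#' @param n_boot Bootstrap resamples (default 2000); 0 skips uncertainty.
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `ci_low`, `ci_high`, `r2`, `p_value`, `n`, `degenerate`.
#' @examples
#' repeated_median_fit(c(0, 1, 2, 3), c(0, 1, 2, 100), n_boot = 0)$slope  # 1
#' @export
repeated_median_fit <- function(x, y, n_boot = 2000L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 points")
  if (length(unique(x)) < 3L) stop("need at least 3 distinct x values")

  est <- function(x, y) {
    dx <- outer(x, x, "-")          # dx[j, i] = x_j - x_i
    dy <- outer(y, y, "-")
    sl <- dy / dx
    diag(sl) <- NA
    sl[dx == 0] <- NA
    inner <- apply(sl, 2, stats::median, na.rm = TRUE)
    slope <- stats::median(inner, na.rm = TRUE)
    intercept <- stats::median(y - slope * x)
    c(slope, intercept)
  }
  fit <- est(x, y)
  slope <- fit[1L]; intercept <- fit[2L]
  res <- y - (intercept + slope * x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  degenerate <- !is.finite(r2) || r2 < 0 || r2 > 1

  ci_low <- ci_high <- p_value <- NA_real_
  if (n_boot > 0L) {
    set.seed(seed)
    bs <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[idx])) < 3L) next
      bs[b] <- est(x[idx], y[idx])[1L]
    }
    bs <- bs[is.finite(bs)]
    if (length(bs) >= 100L) {
      qs <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
      ci_low <- qs[1L]; ci_high <- qs[2L]
      p_raw <- 2 * min(mean(bs <= 0), mean(bs >= 0))
      p_value <- max(min(p_raw, 1), 1 / length(bs))
    }
  }
  structure(list(slope = slope, intercept = intercept,
                 ci_low = ci_low, ci_high = ci_high, r2 = r2,
                 p_value = p_value, n = n, degenerate = degenerate),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.4g [%.4g, %.4g], intercept %.4g, R2 %.3f, p %.4g, n %d%s\n",
              x$slope, x$ci_low, x$ci_high, x$intercept, x$r2, x$p_value, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
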