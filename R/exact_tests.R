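# Exact nonparametric tests used by the kinetics and pairwise modules.
# Implemented in-package so the tie-handling and enumeration rules are
# explicit and testable against independent oracles.

#' Exact Wilcoxon signed-rank test (paired, ties allowed)
#'
#' Tests the paired differences `x - y`. Zero differences are dropped;
#' absolute differences are mid-ranked; the statistic is the sum of ranks
#' of positive differences. For `n <= exact_limit` non-zero pairs the null
#' distribution is enumerated exactly by dynamic programming over the
#' (doubled, hence integer) mid-ranks, which is valid with ties; above the
#' limit a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"less"` (x shifted below y), `"greater"`, or
#'   `"two.sided"`.
#' @param exact_limit Largest n for exact enumeration (default 25).
#' @return List with `statistic` (V), `p_value`, `n` (non-zero pairs),
#'   `exact` (logical) and `degenerate` (TRUE when all differences are 0).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("less", "greater", "two.sided"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("paired values must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                exact = TRUE, degenerate = TRUE))
  }
  r <- rank(abs(d))                       # mid-ranks
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    # DP over doubled ranks: P(V' = k), V' = 2V, k = 0..2*sum(r)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L); f[1L] <- 1
    for (ri in r2) {
      g <- f
      shifted <- c(rep(0, ri), f[seq_len(total + 1L - ri)])
      f <- g + shifted
    }
    probs <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    list(statistic = V, p_value = p, n = n, exact = TRUE, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    p <- switch(alternative,
                less = stats::pnorm((V - mu + cc) / sqrt(sig2)),
                greater = stats::pnorm((V - mu - cc) / sqrt(sig2),
                                       lower.tail = FALSE),
                two.sided = min(1, 2 * min(
                  stats::pnorm((V - mu + cc) / sqrt(sig2)),
                  stats::pnorm((V - mu - cc) / sqrt(sig2), lower.tail = FALSE))))
    list(statistic = V, p_value = p, n = n, exact = FALSE, degenerate = FALSE)
  }
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities not exceeding the observed table's probability (with the
#' customary `1 + 1e-7` tolerance for floating-point equality).
#'
#' @param tab A 2x2 matrix of non-negative counts.
#' @return List with `p_value` and `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    stop("tab must be a 2x2 matrix of non-negative integers")
  }
  m <- sum(tab[1L, ]); n2 <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  if (m + n2 == 0L || k == 0L || k == m + n2) {
    if (sum(tab) == 0L) stop("empty table")
  }
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), table = tab)
}
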