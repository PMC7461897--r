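# Self-contained rank and multiplicity procedures used by the pipeline.

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midranks for ties. The statistic is the sum
#' of the ranks of `x` in the pooled sample. With `mode = "exact"` (the
#' default for pooled sizes up to 12) the p-value is computed by full
#' enumeration of all ways to choose the `x` positions among the pooled
#' ranks, which is valid with or without ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x,y Nonempty numeric samples.
#' @param mode `"auto"` (exact when `length(x) + length(y) <= 12`),
#'   `"exact"` or `"normal"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_limit Pooled-size cutoff for automatic exact enumeration.
#' @return An object of class `htest` with the rank-sum statistic `W`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")$p.value  # 1/6
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal"),
                              alternative = c("two.sided", "less", "greater"),
                              exact_limit = 12L) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))            # midranks
  w <- sum(r[seq_len(nx)])
  if (mode == "auto") mode <- if (N <= exact_limit) "exact" else "normal"

  if (mode == "exact") {
    sets <- utils::combn(N, nx)
    sums <- colSums(matrix(r[sets], nrow = nx))
    eps <- 1e-9
    p_less <- mean(sums <= w + eps)
    p_greater <- mean(sums >= w - eps)
    p <- switch(alternative,
                less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    method <- "Wilcoxon rank-sum test (exact enumeration)"
  } else {
    mu <- nx * (N + 1) / 2
    ties <- table(r)
    v <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (v <= 0) {  # all values tied
      p <- 1
    } else {
      cc <- 0.5
      z_less <- (w - mu + cc) / sqrt(v)
      z_greater <- (w - mu - cc) / sqrt(v)
      p <- switch(alternative,
                  less = stats::pnorm(z_less),
                  greater = stats::pnorm(z_greater, lower.tail = FALSE),
                  two.sided = min(1, 2 * min(stats::pnorm(z_less),
                                             stats::pnorm(z_greater,
                                                          lower.tail = FALSE))))
    }
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  structure(list(
    statistic = c(W = w),
    p.value = p,
    alternative = alternative,
    method = method,
    data.name = sprintf("x (n=%d), y (n=%d)", nx, ny)
  ), class = "htest")
}

#' Mann-Kendall trend test
#'
#' Nonparametric trend test on an ordered sequence:
#' `S = sum over i < j of sign(x_j - x_i)`, tie-corrected variance
#' `(n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18` over tie groups of size t, and
#' a continuity-corrected Z with two-sided normal p-value. Used for the
#' trend of gap times with the accumulation of conditions.
#'
#' @param x Numeric sequence of length >= 3, in its natural order.
#' @return An object of class `htest` with components `statistic` (Z),
#'   `estimate` (S) and `p.value`.
#' @export
#' @examples
#' mann_kendall(c(1, 2, 3, 4))$estimate  # S = 6
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("sequence must have length >= 3")
  if (any(!is.finite(x))) stop("sequence must be finite")
  d <- sign(outer(x, x, "-"))        # d[i, j] = sign(x_i - x_j)
  s <- sum(d[lower.tri(d)])          # sum over i > j, i.e. sign(x_j' - x_i') for i' < j'
  ties <- table(x)
  v <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (s - sign(s)) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(
    statistic = c(Z = z),
    estimate = c(S = s),
    p.value = min(1, p),
    method = "Mann-Kendall trend test",
    data.name = sprintf("sequence of length %d", n)
  ), class = "htest")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values p(1) <= ... <= p(m), reject all
#' hypotheses with index up to the largest i such that p(i) <= i * q / m.
#' Adjusted q-values use the standard monotone cumulative-minimum
#' construction; tied p-values share a rank and therefore a decision.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA not allowed).
#' @param q Target FDR level in (0, 1) (default 0.05).
#' @return List with logical `reject` and numeric `q_value`, both in the
#'   input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)$reject
benjamini_hochberg <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (!length(p)) return(list(reject = logical(0), q_value = numeric(0)))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qv_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  qv_sorted <- pmin(qv_sorted, 1)
  cutoff_idx <- which(ps <= seq_len(m) * q / m)
  reject_sorted <- if (length(cutoff_idx)) seq_len(m) <= max(cutoff_idx) else
    rep(FALSE, m)
  reject <- logical(m); q_value <- numeric(m)
  reject[o] <- reject_sorted
  q_value[o] <- qv_sorted
  list(reject = reject, q_value = q_value)
}
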