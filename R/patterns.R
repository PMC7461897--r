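# Multimorbidity pattern mining: combinations (unordered) and permutations
# (ordered) of the first k conditions, at condition or group level, plus
# contribution-by-rank tables.

#' Multimorbidity pattern table
#'
#' For every person with at least `k` onsets, takes the conditions at ranks
#' 1..k and counts the resulting patterns. With `ordered = TRUE` the onset
#' order is kept (permutations); with `ordered = FALSE` each key is sorted
#' into canonical order and aggregates all its orderings (combinations).
#' With `level = "group"` conditions are first mapped to their six groups;
#' group keys are multisets, so two distinct cardiometabolic conditions form
#' the pattern `CMD|CMD` rather than collapsing to a single `CMD`.
#'
#' Percentages are over the persons with >= k conditions. Patterns rarer
#' than `min_count` persons carry a `suppressed` flag; [write_pattern_table()]
#' omits them from public output, mirroring small-cell confidentiality
#' suppression, but they are retained here so counts and percentages always
#' total the eligible population.
#'
#' @param trajectories An `mm_trajectories` data frame.
#' @param k Pattern size, 2..4.
#' @param level `"condition"` (10 codes) or `"group"` (6 groups).
#' @param ordered Keep onset order (permutations) or not (combinations).
#' @param min_count Suppression threshold (default 5).
#' @return Data frame of class `mm_pattern_table` with columns pattern
#'   (codes pipe-joined), count, pct, suppressed; attributes k, level,
#'   ordered, n_eligible.
#' @export
#' @examples
#' ev <- data.frame(person_id = rep(1:3, each = 2),
#'                  condition = c("ASTHMA", "CVD", "CVD", "ASTHMA",
#'                                "ASTHMA", "CVD"),
#'                  onset_time = c(1, 2, 1, 2, 1, 2))
#' tr <- build_trajectories(ev)
#' pattern_table(tr, k = 2, ordered = TRUE, min_count = 1)
pattern_table <- function(trajectories, k, level = c("condition", "group"),
                          ordered = FALSE, min_count = 5L) {
  level <- match.arg(level)
  if (!k %in% 2:4) stop("k must be 2, 3 or 4")
  tab <- trajectories[trajectories$rank <= k, , drop = FALSE]
  n_ranks <- tapply(tab$rank, tab$person_id, length)
  eligible <- as.numeric(names(n_ranks))[n_ranks == k]
  n_eligible <- length(eligible)

  if (n_eligible == 0L) {
    out <- data.frame(pattern = character(0), count = integer(0),
                      pct = numeric(0), suppressed = logical(0))
  } else {
    tab <- tab[tab$person_id %in% eligible, , drop = FALSE]
    tab <- tab[order(tab$person_id, tab$rank), , drop = FALSE]
    codes <- tab$condition
    vocab <- MM_CONDITIONS
    if (level == "group") {
      codes <- condition_to_group(codes)
      vocab <- MM_GROUPS
    }
    m <- matrix(codes, ncol = k, byrow = TRUE)
    if (!ordered) {
      idx <- matrix(match(m, vocab), ncol = k)
      sorted <- apply(idx, 1L, sort.int)      # k x n: each column a sorted row
      m <- t(matrix(vocab[sorted], nrow = k))
    }
    key <- do.call(paste, c(lapply(seq_len(k), function(j) m[, j]), sep = "|"))
    cnt <- table(key)
    # sort by count desc, then canonical order of the key components
    comp <- do.call(rbind, strsplit(names(cnt), "|", fixed = TRUE))
    comp_idx <- matrix(match(comp, vocab), nrow = nrow(comp))
    kord <- do.call(order, c(list(-as.integer(cnt)),
                             lapply(seq_len(k), function(j) comp_idx[, j])))
    cnt <- cnt[kord]
    out <- data.frame(pattern = names(cnt),
                      count = as.integer(cnt),
                      pct = 100 * as.integer(cnt) / n_eligible,
                      suppressed = as.integer(cnt) < min_count,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "level") <- level
  attr(out, "ordered") <- ordered
  attr(out, "n_eligible") <- n_eligible
  attr(out, "min_count") <- min_count
  class(out) <- c("mm_pattern_table", "data.frame")
  out
}

#' @export
print.mm_pattern_table <- function(x, n = 10L, ...) {
  cat(sprintf("%s patterns of the first %d conditions (%s level), %d persons with >= %d conditions\n",
              if (attr(x, "ordered")) "Ordered" else "Unordered",
              attr(x, "k"), attr(x, "level"), attr(x, "n_eligible"),
              attr(x, "k")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more patterns\n")
  invisible(x)
}

#' Contribution of each condition by ordinal rank
#'
#' Counts how often each condition occurs as the primary, secondary,
#' tertiary and quaternary condition, with percentages summing to 100 within
#' each rank. All ten conditions are listed at every rank (zero counts
#' included).
#'
#' @param trajectories An `mm_trajectories` data frame.
#' @param max_rank Highest rank tabulated (default 4).
#' @return Data frame with columns condition, rank, count, pct.
#' @export
contribution_by_rank <- function(trajectories, max_rank = 4L) {
  tab <- trajectories[trajectories$rank <= max_rank, , drop = FALSE]
  cnt <- table(factor(tab$condition, levels = MM_CONDITIONS),
               factor(tab$rank, levels = seq_len(max_rank)))
  tot <- colSums(cnt)
  out <- data.frame(
    condition = rep(MM_CONDITIONS, max_rank),
    rank = rep(seq_len(max_rank), each = length(MM_CONDITIONS)),
    count = as.integer(cnt),
    pct = as.numeric(100 * sweep(cnt, 2L, pmax(tot, 1L), "/")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test of homogeneity
#'
#' Pearson statistic sum((O - E)^2 / E) on an r x c count table with
#' df = (r - 1)(c - 1), upper-tail p-value and no continuity correction.
#' Used to compare the contribution of each condition between primary and
#' secondary onsets (a 2 x k table of counts).
#'
#' @param x Matrix of nonnegative counts.
#' @return An object of class `htest`.
#' @export
#' @examples
#' chi_square_test(rbind(c(20, 10), c(10, 20)))
chi_square_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be finite and nonnegative")
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in count table")
  e <- outer(rs, cs) / n
  stat <- sum((x - e)^2 / e)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  structure(list(
    statistic = c(`X-squared` = stat),
    parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    method = "Pearson chi-square test of homogeneity",
    data.name = deparse(substitute(x))
  ), class = "htest")
}

#' Cochran-Armitage test for trend in proportions
#'
#' Tests for a linear trend in the success proportion across ordered levels,
#' with equally spaced integer scores by default. The statistic is
#' `Z = sum(s_i * (x_i - n_i * pbar)) / sqrt(pbar * (1 - pbar) *
#' (sum(n_i s_i^2) - (sum(n_i s_i))^2 / N))`; proportions increasing with
#' the level give Z > 0. Two-sided p-value from the normal distribution.
#'
#' @param successes Integer vector of success counts per level (ordered).
#' @param totals Integer vector of trials per level.
#' @param scores Numeric scores for the levels (default 1..k).
#' @return An object of class `htest` with the Z statistic.
#' @export
cochran_armitage <- function(successes, totals, scores = seq_along(successes)) {
  if (length(successes) < 3L) stop("need at least 3 ordered levels")
  if (length(totals) != length(successes) || length(scores) != length(successes))
    stop("successes, totals and scores must have equal length")
  if (any(successes < 0) || any(successes > totals)) stop("invalid counts")
  N <- sum(totals)
  X <- sum(successes)
  if (X == 0 || X == N) stop("all-success or all-failure input: trend undefined")
  pbar <- X / N
  num <- sum(scores * (successes - totals * pbar))
  v <- pbar * (1 - pbar) * (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  z <- num / sqrt(v)
  structure(list(
    statistic = c(Z = z),
    p.value = 2 * stats::pnorm(-abs(z)),
    method = "Cochran-Armitage test for trend",
    data.name = paste(length(successes), "ordered levels")
  ), class = "htest")
}
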