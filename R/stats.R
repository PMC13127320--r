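#' Exact binomial test
#'
#' Exact tail probability of observing `k` or a more extreme count out of
#' `n` under success probability `p0`, computed from the binomial mass
#' function (no normal approximation).
#'
#' @param k Observed successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param direction `"greater"` (default, the superiority direction),
#'   `"less"`, or `"two.sided"`.
#' @return The exact p-value.
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5,
                                direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  if (k < 0 || k > n || n < 1) abort_domain("need 0 <= k <= n, n >= 1")
  stats::binom.test(k, n, p = p0, alternative = direction)$p.value
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from the beta-quantile representation; the lower bound is 0 when
#' `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (k < 0 || k > n || n < 1) abort_domain("need 0 <= k <= n, n >= 1")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the probability-ordering definition: the sum of
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed table.
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    abort_domain("`table` must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_domain("degenerate table: a margin is zero")
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Power of the exact one-sided binomial superiority test
#'
#' Finds the smallest critical count `k*` whose null tail probability does
#' not exceed `alpha`, and evaluates the tail at the alternative.
#'
#' @param n Sample size.
#' @param p0 Null proportion.
#' @param p1 Alternative proportion.
#' @param alpha One-sided significance level.
#' @return A tibble with `n`, `critical_k`, `achieved_size`, `power`, and
#'   `alpha_reachable` (FALSE when even `k = n` cannot reach `alpha`; power
#'   is then the strict test's power at that degenerate critical value, 0
#'   when no rejection is possible).
#' @export
exact_binomial_power <- function(n, p0 = 0.5, p1 = 0.65, alpha = 0.025) {
  if (n < 1 || p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1 ||
      alpha <= 0 || alpha >= 1) {
    abort_domain("invalid binomial test specification")
  }
  tails <- stats::pbinom(0:n - 1, n, p0, lower.tail = FALSE) # P(X >= k), k=0..n
  ok <- which(tails <= alpha)
  if (length(ok) == 0L) {
    return(tibble::tibble(n = n, critical_k = NA_integer_, achieved_size = 0,
                          power = 0, alpha_reachable = FALSE))
  }
  kstar <- min(ok) - 1L
  tibble::tibble(
    n = n, critical_k = kstar,
    achieved_size = stats::pbinom(kstar - 1, n, p0, lower.tail = FALSE),
    power = stats::pbinom(kstar - 1, n, p1, lower.tail = FALSE),
    alpha_reachable = TRUE
  )
}

#' Location-adjusted k-sample Ansari-Bradley scale test
#'
#' Tests for heterogeneity in dispersion across two or more groups: each
#' group is centred at its median, the centred values are pooled and ranked,
#' Ansari-Bradley scores (symmetric ranks counted from both ends, midranks
#' for ties) are assigned, and a chi-square statistic of the
#' Kruskal-Wallis type is formed on the scores. For small pooled samples an
#' exact permutation p-value over group relabellings is available.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; at least 2 groups of
#'   size >= 2.
#' @param location_adjust How to align locations before scoring (currently
#'   `"median"`).
#' @param exact Compute an exact permutation p-value; defaults to pooled
#'   n <= 12. Random permutations are never used: all assignments are
#'   enumerated.
#' @return A tibble with `statistic`, `df`, `p_value`, `method`, and
#'   `degenerate` (TRUE when some group is constant after centring).
#' @export
ansari_bradley_scale_test <- function(values, groups, location_adjust = "median",
                                      exact = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) abort_domain("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) abort_domain("every group needs >= 2 values")
  location_adjust <- match.arg(location_adjust, "median")
  centred <- unsplit(lapply(split(values, groups), function(v) v - stats::median(v)),
                     groups)
  degenerate <- any(vapply(split(centred, groups), function(v) all(v == v[1]),
                           logical(1)))
  n <- length(centred)
  exact <- exact %||% (n <= 12L)
  stat_fun <- function(g) {
    r <- rank(centred)                     # midranks for ties
    a <- pmin(r, n + 1 - r)                # Ansari-Bradley scores
    abar <- mean(a)
    v <- sum((a - abar)^2) / (n - 1)
    if (v == 0) return(c(stat = 0))
    ni <- tabulate(g)
    gm <- vapply(split(a, g), mean, numeric(1))
    c(stat = sum(ni * (gm - abar)^2) / v)
  }
  stat <- stat_fun(groups)[["stat"]]
  df <- nlevels(groups) - 1L
  if (exact) {
    # enumerate all distinct assignments of observations to group sizes
    perms <- utils::combn(n, tabulate(groups)[1])
    if (nlevels(groups) == 2L) {
      stats_all <- apply(perms, 2, function(ix) {
        g <- factor(ifelse(seq_len(n) %in% ix, levels(groups)[1], levels(groups)[2]),
                    levels = levels(groups))
        stat_fun(g)[["stat"]]
      })
      p <- mean(stats_all >= stat - 1e-12)
      method <- "exact permutation"
    } else {
      p <- stats::pchisq(stat, df, lower.tail = FALSE)
      method <- "chi-square approximation"
    }
  } else {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  tibble::tibble(statistic = stat, df = df, p_value = p, method = method,
                 degenerate = degenerate)
}
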