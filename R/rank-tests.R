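#' Midranks of a numeric vector
#'
#' Assigns ranks to pooled observations, with tied values receiving the
#' average of the ranks they span (the convention underlying the
#' Mann-Whitney U statistic). Ranks always sum to `N(N+1)/2`.
#'
#' @param values Numeric vector, all finite.
#' @return Numeric vector of midranks, same length as `values`.
#' @examples
#' midranks(c(3, 1, 2))   # 3 1 2
#' midranks(c(5, 5))      # 1.5 1.5
#' @export
midranks <- function(values) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (length(values) && any(!is.finite(values))) {
    stop("`values` must be finite")
  }
  rank(values, ties.method = "average")
}

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for group sizes `n1` and `n2` with no ties, the number of rank
#' assignments yielding each value of U, by the standard recursive counting
#' method: `N[m, n](u) = N[m-1, n](u - n) + N[m, n-1](u)`.
#'
#' @param n1,n2 Group sizes (positive integers).
#' @return A data frame with columns `u` (0 to `n1*n2`) and `prob`, the
#'   exact null probability `P(U = u)`; probabilities sum to 1.
#' @export
exact_u_distribution <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  umax <- n1 * n2
  # tab[n + 1, u + 1] = N[m, n](u); rebuilt for m = 0, 1, ..., n1 using
  # N[m, n](u) = N[m, n-1](u) + N[m-1, n](u - n)
  tab <- matrix(0, nrow = n2 + 1, ncol = umax + 1)
  tab[, 1] <- 1                       # m = 0: all mass at U = 0 for every n
  for (m in seq_len(n1)) {
    nxt <- matrix(0, nrow = n2 + 1, ncol = umax + 1)
    nxt[1, 1] <- 1                    # n = 0
    for (n in seq_len(n2)) {
      shifted <- c(rep(0, n), tab[n + 1, seq_len(umax + 1 - n)])
      nxt[n + 1, ] <- nxt[n, ] + shifted
    }
    tab <- nxt
  }
  counts <- tab[n2 + 1, ]
  total <- choose(n1 + n2, n1)
  data.frame(u = 0:umax, prob = counts / total)
}

#' Mann-Whitney U test for two independent groups
#'
#' Computes the U statistic for `group_a` from midrank sums, the
#' tie-corrected standard normal deviate without continuity correction,
#' the asymptotic two-sided p-value, and the exact two-sided p-value
#' (full enumeration of the U null distribution when there are no ties,
#' complete permutation otherwise). The two-sided exact p is the doubled
#' smaller tail, capped at 1.
#'
#' The variance of U under the null is
#' `sigma^2 = (n1 n2 / 12) * ((N + 1) - sum(t^3 - t) / (N (N - 1)))`
#' with the sum over tie-group sizes `t`.
#'
#' @param group_a,group_b Numeric vectors of observations (finite, nonempty).
#'   `u` is reported for `group_a`.
#' @param max_permutations Upper bound on `choose(N, n_a)` for the exact
#'   permutation computation under ties; beyond it `p_exact` is `NA` with a
#'   warning. Default 2e6.
#' @return An object of class `rank_test_result`: a list with `n1`, `n2`,
#'   `u`, `mean_rank_1`, `mean_rank_2`, `z`, `p_exact`, `p_asymptotic`,
#'   `tie_corrected`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6, 7))
#' @export
mann_whitney <- function(group_a, group_b, max_permutations = 2e6) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty")
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  N <- n1 + n2
  pooled <- c(group_a, group_b)
  r <- midranks(pooled)
  r_a <- sum(r[seq_len(n1)])
  u <- r_a - n1 * (n1 + 1) / 2
  mean_rank_1 <- r_a / n1
  mean_rank_2 <- (N * (N + 1) / 2 - r_a) / n2

  ties <- table(pooled)
  tie_sizes <- as.numeric(ties[ties > 1])
  tie_term <- if (length(tie_sizes)) sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)) else 0
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else NA_real_
  p_asymptotic <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))

  has_ties <- length(tie_sizes) > 0
  if (!has_ties) {
    dist <- exact_u_distribution(n1, n2)
    lower <- sum(dist$prob[dist$u <= u])
    upper <- sum(dist$prob[dist$u >= u])
    p_exact <- min(1, 2 * min(lower, upper))
  } else {
    n_comb <- choose(N, n1)
    if (n_comb > max_permutations) {
      warning("too many permutations for exact p under ties; returning NA")
      p_exact <- NA_real_
    } else {
      combs <- utils::combn(N, n1)
      u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
      lower <- mean(u_all <= u)
      upper <- mean(u_all >= u)
      p_exact <- min(1, 2 * min(lower, upper))
    }
  }

  structure(
    list(n1 = n1, n2 = n2, u = u,
         mean_rank_1 = mean_rank_1, mean_rank_2 = mean_rank_2,
         z = z, p_exact = p_exact, p_asymptotic = p_asymptotic,
         tie_corrected = has_ties),
    class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test: n = %d vs %d\n", x$n1, x$n2))
  cat(sprintf("  U = %g, mean ranks %.2f / %.2f\n",
              x$u, x$mean_rank_1, x$mean_rank_2))
  cat(sprintf("  z = %.3f, p (asymptotic) = %.4g, p (exact) = %.4g\n",
              x$z, x$p_asymptotic, x$p_exact))
  invisible(x)
}

#' Mean rank of a group from its U statistic
#'
#' Recovers a group's mean midrank from its U statistic:
#' `(u + n(n+1)/2) / n` for group size `n` in a pooled sample of `n_total`.
#'
#' @param u U statistic for the group (0 to `n_group * (n_total - n_group)`).
#' @param n_group Size of the group.
#' @param n_total Total pooled sample size.
#' @return The group's mean rank.
#' @examples
#' mean_rank_from_u(10, 6, 19)  # 5.1667
#' @export
mean_rank_from_u <- function(u, n_group, n_total) {
  if (u < 0 || u > n_group * (n_total - n_group)) {
    stop("`u` out of range for the given group sizes")
  }
  (u + n_group * (n_group + 1) / 2) / n_group
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric point probabilities, with margins fixed, over all
#' tables whose point probability does not exceed that of the observed
#' table (with a 1 + 1e-7 relative guard against floating-point ties).
#' Point probabilities are evaluated in log space via `lchoose`, which is
#' numerically stable through n of several hundred.
#'
#' @param a,b,c,d Nonnegative integer cell counts, table rows `(a, b)` and
#'   `(c, d)`.
#' @return Two-sided p-value. A table with a zero margin returns 1.
#' @examples
#' fisher_exact_2x2(8, 5, 4, 2)   # 1
#' fisher_exact_2x2(5, 8, 1, 5)   # 0.605
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers")
  }
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- logp[support == a]
  sum(exp(logp[exp(logp) <= exp(p_obs) * (1 + 1e-7)]))
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' Sample correlation with the p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return A list with `r`, `p`, `n`, `df`, `t`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    tstat <- Inf * sign(r)
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, df = n - 2, t = tstat)
}
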