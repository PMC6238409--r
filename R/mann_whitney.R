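# Rank sums of every k-subset of v, by recursion (no combn): the subset
# either contains v[1] or not.
.subset_sums <- function(v, k) {
  if (k == 0L) return(0)
  if (length(v) == k) return(sum(v))
  c(.subset_sums(v[-1L], k), v[1L] + .subset_sums(v[-1L], k - 1L))
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes the two-sided p-value as twice the smaller one-sided tail
#' probability, capped at 1. For `n_a + n_b <= max_exact` the null
#' distribution of the rank sum is obtained by full enumeration of all
#' `choose(n, n_a)` rank assignments (ties handled with midranks, so the
#' enumeration is over the observed tied rank multiset -- a permutation
#' test); above that a normal approximation with tie and continuity
#' correction is used and flagged.
#'
#' @param group_a,group_b Numeric vectors (non-empty, no `NA`).
#' @param max_exact Largest pooled size for exact enumeration (default 12).
#' @return A list of class `mw_test`: `p_value`, `statistic` (U of group
#'   a), `exact`, `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))$p_value # 0.0079
mann_whitney_exact <- function(group_a, group_b, max_exact = 12L) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    abort("groups must not contain undefined values")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  ranks <- rank(pooled) # midranks for ties
  w_obs <- sum(ranks[seq_len(n_a)])
  u_obs <- w_obs - n_a * (n_a + 1) / 2
  eps <- 1e-9
  if (n_a + n_b <= max_exact) {
    sums <- .subset_sums(ranks, n_a)
    p_low <- mean(sums <= w_obs + eps)
    p_high <- mean(sums >= w_obs - eps)
    p <- min(1, 2 * min(p_low, p_high))
    exact <- TRUE
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    tie_sizes <- table(pooled)
    tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
    method <- "normal approximation (tie and continuity corrected)"
  }
  structure(
    list(p_value = p, statistic = u_obs, exact = exact, method = method,
         n_a = n_a, n_b = n_b),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %.1f, two-sided p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' @rdname mann_whitney_exact
#' @param x A `mw_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mw_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, exact = x$exact,
         method = x$method, n_a = x$n_a, n_b = x$n_b)
}
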