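#' Exact Wilcoxon signed-rank test for small paired samples
#'
#' Paired two-tailed signed-rank test with an exact null distribution
#' obtained by enumerating all `2^n` sign patterns (equivalently, by the
#' generating-function recursion over the observed midranks, which handles
#' tied absolute differences exactly). Zero differences are dropped before
#' ranking, with the dropped count reported. The reported statistic is the
#' min-tail rank sum `W = min(W+, W-)`; the exact two-tailed p-value is
#' twice the lower-tail probability `P(W+ <= W)` under the sign-flip null,
#' capped at 1.
#'
#' @param x numeric vector: paired differences, or the first member of
#'   each pair when `y` is given.
#' @param y optional numeric vector paired with `x`; differences are
#'   `x - y`.
#' @return An object of class `rank_test_result`: list with `statistic`
#'   (min-tail W), `n` (non-zero pairs), `n_zero` (dropped), and
#'   `p_two_tailed`, `method = "signed_rank"`.
#' @export
signed_rank_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y))
      stop("paired samples must have equal length", call. = FALSE)
    as.numeric(x) - as.numeric(y)
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  if (n > 20)
    stop("exact enumeration supports at most 20 non-zero pairs",
         call. = FALSE)
  r <- rank(abs(d))                       # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r) - w_plus
  w <- min(w_plus, w_minus)
  # Null distribution of 2*W+ (doubled so midranks become integers):
  # generating-function convolution over the n independent sign flips.
  r2 <- as.integer(round(2 * r))
  total2 <- sum(r2)
  p <- numeric(total2 + 1)                # index k+1 holds P(2W+ = k)
  p[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), p[seq_len(total2 + 1 - rr)])
    p <- (p + shifted) / 2
  }
  w2 <- as.integer(round(2 * w))
  p_low <- sum(p[seq_len(w2 + 1)])
  structure(list(statistic = w, n = n, n_zero = n_zero,
                 p_two_tailed = min(1, 2 * p_low), method = "signed_rank"),
            class = "rank_test_result")
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test for small samples
#'
#' Two-sample two-tailed rank-sum test with an exact null distribution
#' obtained by complete enumeration of all `choose(n + m, n)` allocations
#' of the observed midranks to group A (ties handled exactly). The
#' reported statistic is the min-tail Mann-Whitney count
#' `U = min(U_A, U_B)`; the exact two-tailed p-value is twice the
#' lower-tail probability `P(U_A <= U)` under the permutation null,
#' capped at 1. Complete group separation with n = m = 5 gives U = 0 and
#' p = 2/252.
#'
#' @param a,b numeric vectors; `length(a) + length(b) <= 20`.
#' @return An object of class `rank_test_result`: list with `statistic`
#'   (min-tail U), `n`, `m`, `p_two_tailed`, `method = "rank_sum"`.
#' @export
rank_sum_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0)
    stop("validation error: both groups must be nonempty", call. = FALSE)
  if (n + m > 20)
    stop("exact enumeration supports at most 20 observations in total",
         call. = FALSE)
  r <- rank(c(a, b))                      # midranks for ties
  u_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_b <- n * m - u_a
  u <- min(u_a, u_b)
  alloc <- utils::combn(n + m, n)         # every allocation of ranks to A
  u_all <- colSums(matrix(r[alloc], nrow = n)) - n * (n + 1) / 2
  p_low <- mean(u_all <= u + 1e-9)
  structure(list(statistic = u, n = n, m = m,
                 p_two_tailed = min(1, 2 * p_low), method = "rank_sum"),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  sizes <- if (x$method == "rank_sum") sprintf("n = %d, m = %d", x$n, x$m)
           else sprintf("n = %d (%d zero pairs dropped)", x$n, x$n_zero)
  cat(sprintf("<rank_test_result> %s: statistic = %g, %s, p = %.5g (exact, two-tailed)\n",
              x$method, x$statistic, sizes, x$p_two_tailed))
  invisible(x)
}

#' Mean and standard error of a sample
#'
#' Sample mean with standard error `sd / sqrt(n)` using the n - 1
#' denominator — the "mean +/- S.E." summary used for per-animal result
#' columns.
#'
#' @param values numeric vector, `length >= 2`.
#' @return list with `mean` and `se`.
#' @export
mean_se <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("validation error: need at least 2 values", call. = FALSE)
  list(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}
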