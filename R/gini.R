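#' Gini coefficient of a nonnegative expression vector
#'
#' Measures inequality of expression across samples: 0 when every sample has
#' the same TPM, approaching 1 when all expression is concentrated in a single
#' sample. Computed with the classical sorted-index (population) formula
#' \deqn{G = \sum_i (2i - n - 1)\, x_{(i)} / (n S)}
#' for sorted values \eqn{x_{(1)} \le \dots \le x_{(n)}} with total
#' \eqn{S = \sum_i x_i}. No small-sample correction is applied, so the
#' attainable maximum is \eqn{(n-1)/n} (a one-hot vector).
#'
#' Zeros are legitimate observations (undetectable expression); the statistic
#' is undefined (`NA`) when the vector sums to zero or has fewer than two
#' entries.
#'
#' @param x numeric vector of nonnegative, finite values (raw TPM).
#' @return A single numeric value in `[0, (n-1)/n]`, or `NA_real_` when
#'   undefined.
#' @seealso [gini_pairwise_oracle()] for the brute-force cross-check,
#'   [lorenz_points()] for the underlying curve.
#' @examples
#' gini(c(5, 5, 5, 5))   # 0: perfect equality
#' gini(c(0, 0, 0, 1))   # 0.75: one-hot maximum at n = 4
#' @export
gini <- function(x) {
  check_nonnegative(x)
  n <- length(x)
  s <- sum(x)
  if (n < 2L || s <= 0) {
    return(NA_real_)
  }
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * s)
}

#' Brute-force pairwise Gini (independent oracle)
#'
#' Mean-absolute-difference formulation
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar{x})}, quadratic in the
#' number of samples. Kept as an independent reference implementation for
#' validating [gini()]; the two agree to floating-point precision on every
#' admissible input.
#'
#' @inheritParams gini
#' @return As [gini()].
#' @export
gini_pairwise_oracle <- function(x) {
  check_nonnegative(x)
  n <- length(x)
  s <- sum(x)
  if (n < 2L || s <= 0) {
    return(NA_real_)
  }
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Lorenz curve points
#'
#' Cumulative share of total expression against cumulative share of samples,
#' sorted ascending, anchored at (0, 0) and (1, 1). Twice the area between
#' the diagonal and the curve equals the Gini coefficient.
#'
#' @inheritParams gini
#' @return `data.frame` with columns `pop_share` and `expr_share`, both
#'   nondecreasing from 0 to 1.
#' @examples
#' lorenz_points(c(1, 1))  # the equality diagonal
#' @export
lorenz_points <- function(x) {
  check_nonnegative(x)
  s <- sum(x)
  if (length(x) < 1L || s <= 0) {
    gd_abort("Lorenz curve undefined for empty or zero-sum input",
             "gd_domain_error")
  }
  xs <- sort(x)
  n <- length(xs)
  data.frame(
    pop_share = c(0, seq_len(n) / n),
    expr_share = c(0, cumsum(xs) / s)
  )
}

#' Z-scores (standard scores)
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (n - 1
#' denominator). When the standard deviation is zero every Z is defined as 0,
#' so constant vectors pass through downstream thresholds harmlessly instead
#' of producing NaN.
#'
#' @param x numeric vector, length >= 2, finite.
#' @return Numeric vector of the same length.
#' @examples
#' zscores(c(1, 2, 3))  # -1 0 1
#' @export
zscores <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    gd_abort("zscores requires a numeric vector of length >= 2",
             "gd_domain_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    gd_abort("zscores input contains missing or non-finite entries",
             "gd_domain_error")
  }
  s <- stats::sd(x)
  if (s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Two-sided standard-normal tail probability
#'
#' `P(|Z| >= z)` for a standard normal variate: the probability attached to a
#' Z cutoff (1.96 corresponds to 5%, 2.58 to 1%).
#'
#' @param z positive numeric threshold(s).
#' @return Probability in (0, 1).
#' @export
two_sided_tail <- function(z) {
  if (!is.numeric(z) || length(z) == 0L || anyNA(z) || any(!is.finite(z)) ||
      any(z <= 0)) {
    gd_abort("two_sided_tail requires positive finite z", "gd_domain_error")
  }
  2 * stats::pnorm(-z)
}

# Row-wise Gini over a genes x samples matrix, honouring an optional logical
# mask (TRUE = value excluded). Returns one value per row (NA when undefined).
row_gini <- function(values, mask = NULL) {
  n <- nrow(values)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- values[i, ]
    if (!is.null(mask)) {
      v <- v[!mask[i, ]]
    }
    out[i] <- gini(v)
  }
  out
}
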