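#' Pearson correlation with exact t-based p-value
#'
#' Computes the sample Pearson correlation between two vectors together
#' with the two-sided p-value from the exact t-transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 4 observations),
#'   both with nonzero variance.
#' @return A list with elements `r` (correlation), `n` (number of paired
#'   observations) and `p` (two-sided p-value of H0: rho = 0).
#' @examples
#' pearson_with_p(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("at least 4 paired observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: an input vector has zero variance")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  list(r = r, n = n, p = cor_p_from_r(r, n))
}

# Two-sided p for a Pearson correlation via the exact t-transform.
# Vectorised over r; |r| = 1 maps to p = 0.
cor_p_from_r <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Test the difference of two correlations by Fisher Z-transformation
#'
#' The two correlation coefficients are variance-stabilised with
#' \eqn{\mathrm{atanh}} and their difference is referred to a standard
#' normal: \eqn{z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
#' \sqrt{1/(n_1-3) + 1/(n_2-3)}}.
#'
#' @param r1,r2 Correlation coefficients with absolute value strictly
#'   below 1.
#' @param n1,n2 Sample sizes of the two groups; both must exceed 3.
#' @return A list with elements `z` (standard-normal deviate) and `p`
#'   (two-sided p-value).
#' @examples
#' fisher_z_diff_test(0.70, 30, -0.19, 22)
#' @export
fisher_z_diff_test <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| = 1: Fisher Z-transform is infinite")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Multiple-testing adjustment of a p-value vector
#'
#' Benjamini-Hochberg step-up false-discovery-rate control or Holm
#' step-down family-wise error control, in the order of the input.
#'
#' @param values Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"Holm"`.
#' @return A list with elements `values`, `adjusted` and `method`.
#' @examples
#' adjust_pvalues(c(0.01, 0.04), method = "Holm")
#' @export
adjust_pvalues <- function(values, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(values, method = c(BH = "BH", Holm = "holm")[method])
  list(values = values, adjusted = adjusted, method = method)
}

#' Upper tail of the binomial distribution
#'
#' Returns \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, rate)};
#' the inclusive upper tail used to test whether a protein carries more
#' differentially co-expressed links than expected under a global rate.
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param rate Success probability.
#' @return The p-value \eqn{P(X \ge k)}.
#' @examples
#' binomial_tail(5, 10, 0.1)
#' @export
binomial_tail <- function(k, n, rate) {
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  stats::pbinom(k - 1, size = n, prob = rate, lower.tail = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' One-sided (`greater`) enrichment is computed as the hypergeometric
#' upper tail; the two-sided test is the standard probability-sum over
#' all tables with the observed margins.
#'
#' @param a,b,c,d Non-negative cell counts. `a` counts the in-category
#'   successes, `b` the out-of-category successes, `c` the in-category
#'   failures and `d` the remainder.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return The p-value.
#' @examples
#' fisher_exact_enrichment(3, 5, 2, 10, alternative = "greater")
#' @export
fisher_exact_enrichment <- function(a, b, c, d,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("all cell counts must be non-negative")
  if (alternative == "greater") {
    stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2),
                       alternative = "two.sided")$p.value
  }
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# with the asymptotic branches used for very large and very small
# arguments. Needed by the empirical-Bayes moment estimator.
trigamma_inverse <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  y <- x
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  mid <- which(x >= 1e-6 & x <= 1e7)
  if (length(mid)) {
    yy <- 0.5 + 1 / x[mid]
    for (i in seq_len(50)) {
      tri <- trigamma(yy)
      dif <- tri * (1 - tri / x[mid]) / psigamma(yy, deriv = 2)
      yy <- yy + dif
      if (max(-dif / yy) < 1e-8) break
    }
    y[mid] <- yy
  }
  y
}
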