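# Independent brute-force oracles for the statistical primitives, and
# small fixture builders. These deliberately use the definitional
# formulas (or exhaustive enumeration), not the code paths they check.

# BH step-up straight from the definition on the sorted p-values
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m),
                function(i) min(1, min(ps[i:m] * m / (i:m))), 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Holm step-down: cumulative max of p_(j) * (m - j + 1)
bf_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, cummax(ps * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive enumeration of all 2x2 tables with the observed margins;
# probabilities from the hypergeometric mass written out in binomial
# coefficients
bf_fisher <- function(a, b, c, d, alternative = "greater") {
  r1 <- a + b
  k <- a + c
  n <- a + b + c + d
  ks <- max(0, k - (n - r1)):min(r1, k)
  pr <- choose(r1, ks) * choose(n - r1, k - ks) / choose(n, k)
  if (alternative == "greater") {
    sum(pr[ks >= a])
  } else {
    sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
  }
}

# pooled-variance two-sample t-test p-value, written out
bf_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# small two-group abundance table with iid normal values
make_table <- function(p = 20, n1 = 6, n2 = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(p * (n1 + n2)), p,
              dimnames = list(sprintf("P%03d", 1:p),
                              c(sprintf("T%02d", 1:n1),
                                sprintf("N%02d", 1:n2))))
  abundance_table(v, structure(c(rep("case", n1), rep("control", n2)),
                               names = colnames(v)))
}

# coex_links scaffold with explicitly chosen statistics, for testing
# the DCL classifier in isolation
make_links <- function(df, proteins) {
  attr(df, "proteins") <- proteins
  attr(df, "n_case") <- 30
  attr(df, "n_ctrl") <- 22
  class(df) <- c("coex_links", "data.frame")
  df
}
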