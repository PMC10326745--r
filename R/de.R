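#' Moderated two-group differential expression
#'
#' Fits, per protein, the ordinary two-group linear model (difference of
#' group means with pooled residual variance on \eqn{n-2} df) and
#' shrinks the residual variances towards a common prior by empirical
#' Bayes. The prior degrees of freedom `d0` and prior variance `s0_sq`
#' are estimated by matching the first two moments of
#' \eqn{\log s_g^2} to the scaled-F model
#' \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)}, using the digamma/trigamma
#' moment equations; when the trigamma equation has no positive root
#' the prior is taken as infinitely informative (`d0 = Inf`). The
#' moderated statistic is
#' \eqn{\tilde t_g = \beta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})} with
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, referred to
#' a t-distribution on \eqn{d_0 + d_g} df.
#'
#' @param x An [abundance_table()] without missing values, with two
#'   groups of at least two samples each. The log2 fold change is
#'   `case` minus `control` (the second group level minus the first when
#'   other labels are used).
#' @param d0 Optional override of the prior degrees of freedom: `0`
#'   yields the ordinary pooled-variance t-test, `Inf` full shrinkage to
#'   the prior variance. By default `d0` is estimated from the data.
#' @param groups Optional length-2 character vector naming the reference
#'   and the test group; defaults to `c("control", "case")`.
#' @return A list with `results` (a data frame with columns `protein`,
#'   `log2fc`, `s2`, `t_mod`, `df_total`, `p`, `fdr`, `status`) and
#'   `prior` (list with `d0` and `s0_sq`).
#' @export
fit_moderated_t <- function(x, d0 = NULL, groups = c("control", "case")) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("missing values must be imputed first")
  g1 <- group_samples(x, groups[1])
  g2 <- group_samples(x, groups[2])
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group needs at least 2 samples")
  }
  v1 <- x$values[, g1, drop = FALSE]
  v2 <- x$values[, g2, drop = FALSE]
  n1 <- length(g1)
  n2 <- length(g2)
  beta <- rowMeans(v2) - rowMeans(v1)
  rss <- rowSums((v1 - rowMeans(v1))^2) + rowSums((v2 - rowMeans(v2))^2)
  dg <- n1 + n2 - 2
  s2 <- rss / dg

  prior <- estimate_eb_prior(s2, dg)
  if (!is.null(d0)) {
    if (d0 < 0) stop("d0 must be non-negative")
    prior$d0 <- d0
  }
  if (all(s2 == 0)) stop("degenerate prior: all residual variances are zero")

  if (prior$d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + dg * s2) / (prior$d0 + dg)
  }
  df_total <- pmin(dg + prior$d0, dg * length(s2))
  t_mod <- beta / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(
    protein = rownames(x$values),
    log2fc = beta, s2 = s2, t_mod = t_mod, df_total = df_total,
    p = p, fdr = stats::p.adjust(p, method = "BH"),
    status = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(results = res, prior = prior)
}

# Closed-form moment estimation of the scaled-F hyperparameters from the
# observed residual variances, on the log scale. Zero variances are
# offset to a small positive fraction of the median so that log s^2 is
# finite; this reproduces the standard behavior of the moderated-t
# estimator.
estimate_eb_prior <- function(s2, dg) {
  x <- pmax(s2, 0)
  m <- stats::median(x)
  if (m == 0) {
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  x <- pmax(x, 1e-5 * m)
  e <- log(x) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(x)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Call differentially expressed proteins
#'
#' Assigns status `up` when `fdr < fdr_cut` and the fold change exceeds
#' `fc_cut` (case over control), `down` for the reciprocal, `ns`
#' otherwise. The fold-change cut is applied on the log2 scale as
#' `|log2fc| > log2(fc_cut)`.
#'
#' @param results The `results` data frame of [fit_moderated_t()].
#' @param fdr_cut FDR threshold (default 0.1).
#' @param fc_cut Fold-change threshold on the natural scale
#'   (default 1.5).
#' @return The data frame with `status` filled in.
#' @export
call_de <- function(results, fdr_cut = 0.1, fc_cut = 1.5) {
  lfc <- log2(fc_cut)
  results$status <- ifelse(
    results$fdr < fdr_cut & results$log2fc > lfc, "up",
    ifelse(results$fdr < fdr_cut & results$log2fc < -lfc, "down", "ns")
  )
  results
}

#' @rdname read_abundance
#' @param results A differential-expression results data frame.
#' @export
write_de_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
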