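#' Consensus clustering of samples
#'
#' Subsampled consensus clustering: for each candidate cluster number
#' `k`, the samples are repeatedly subsampled (without replacement),
#' clustered by agglomerative hierarchical clustering with average
#' linkage on the distance `1 - Pearson correlation`, and the fraction
#' of co-sampled runs in which two samples co-cluster defines the
#' consensus matrix. Final labels come from hierarchical clustering of
#' `1 - consensus` cut at `k`. Features (proteins) are z-scored first
#' so that high-abundance proteins do not dominate the correlation
#' distance. The area under the consensus CDF and its relative increase
#' (delta area) are reported per `k`; `chosen_k` is the largest `k`
#' whose delta area exceeds 0.1 (the conventional elbow reading),
#' overridable via `chosen_k`.
#'
#' @param x An [abundance_table()] (case samples are used when a
#'   two-group design is present) or a numeric features-by-samples
#'   matrix without missing values.
#' @param k_max Largest cluster number evaluated (k = 2..k_max).
#' @param reps Number of subsampling repetitions (default 1000).
#' @param subsample_frac Fraction of samples per repetition.
#' @param seed Random seed.
#' @param chosen_k Optional manual override of the selected k.
#' @param scale_rows Z-score features before clustering.
#' @return An object of class `consensus_result`: list with `k_range`,
#'   `consensus` (per-k matrices), `labels` (per-k assignments),
#'   `cdf_areas`, `delta_areas`, `chosen_k`.
#' @export
consensus_cluster <- function(x, k_max = 6, reps = 1000,
                              subsample_frac = 0.8, seed = 1,
                              chosen_k = NULL, scale_rows = TRUE) {
  if (reps < 10) stop("reps must be at least 10")
  v <- consensus_input_matrix(x, scale_rows)
  n <- ncol(v)
  if (n < 2 * k_max) stop("need at least 2 * k_max samples")
  dist_full <- 1 - stats::cor(v)
  if (!all(is.finite(dist_full))) stop("constant sample detected")
  if (stats::sd(dist_full) == 0) stop("constant distance matrix")
  set.seed(seed)
  k_range <- 2:k_max
  n_sub <- ceiling(subsample_frac * n)
  subsets <- lapply(seq_len(reps), function(i) sort(sample.int(n, n_sub)))
  consensus <- list()
  labels <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    for (ss in subsets) {
      hc <- stats::hclust(stats::as.dist(dist_full[ss, ss]),
                          method = "average")
      cl <- stats::cutree(hc, k = k)
      same <- outer(cl, cl, `==`)
      co[ss, ss] <- co[ss, ss] + same
      tog[ss, ss] <- tog[ss, ss] + 1
    }
    cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(v), colnames(v))
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    labels[[as.character(k)]] <- stats::cutree(hc, k = k)
    consensus[[as.character(k)]] <- cons
  }
  areas <- vapply(consensus, consensus_cdf_area, numeric(1))
  delta <- c(areas[1], diff(areas) / areas[-length(areas)])
  names(delta) <- names(areas)
  auto_k <- {
    ok <- k_range[delta > 0.1]
    if (length(ok)) max(ok) else 2L
  }
  res <- list(k_range = k_range, consensus = consensus, labels = labels,
              cdf_areas = areas, delta_areas = delta,
              chosen_k = if (is.null(chosen_k)) auto_k else chosen_k,
              reps = reps, subsample_frac = subsample_frac, seed = seed)
  class(res) <- "consensus_result"
  res
}

consensus_input_matrix <- function(x, scale_rows) {
  if (inherits(x, "abundance_table")) {
    samples <- if (any(x$design == "case")) group_samples(x, "case")
               else colnames(x$values)
    v <- x$values[, samples, drop = FALSE]
  } else {
    v <- x
  }
  if (anyNA(v)) stop("missing values are not allowed")
  if (scale_rows) {
    keep <- apply(v, 1, stats::sd) > 0
    if (!all(keep)) {
      warning(sum(!keep), " constant feature(s) dropped before clustering")
    }
    v <- t(scale(t(v[keep, , drop = FALSE])))
  }
  v
}

# area under the empirical CDF of the upper-triangle consensus values
consensus_cdf_area <- function(cons) {
  vals <- sort(cons[upper.tri(cons)])
  cdf <- stats::ecdf(vals)
  grid <- sort(unique(c(0, vals, 1)))
  sum(diff(grid) * cdf(grid[-length(grid)]))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k =", paste(range(x$k_range), collapse = ".."),
      sprintf("(%d reps, %.0f%% subsampling)\n",
              x$reps, 100 * x$subsample_frac))
  cat("  CDF areas: ",
      paste(sprintf("k=%s %.3f", names(x$cdf_areas), x$cdf_areas),
            collapse = ", "), "\n")
  cat("  chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Differential expression between two discovered subtypes
#'
#' Applies the moderated-t machinery of [fit_moderated_t()] to the case
#' samples split by subtype label; markers are proteins below the FDR
#' cut (no fold-change cut).
#'
#' @param x An [abundance_table()] (only the labelled samples are
#'   used).
#' @param labels Named vector (sample to subtype) with exactly two
#'   distinct values on two or more samples each.
#' @param fdr_cut Marker FDR threshold (default 0.001).
#' @return The moderated-t results data frame with a logical
#'   `is_marker` column; the fitted prior as `attr(, "prior")`.
#' @export
subtype_markers <- function(x, labels, fdr_cut = 0.001) {
  stopifnot(inherits(x, "abundance_table"))
  labels <- labels[!is.na(labels)]
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("exactly two subtype labels are required")
  if (any(table(labels) < 2)) stop("each subtype needs at least 2 samples")
  samples <- intersect(colnames(x$values), names(labels))
  sub <- abundance_table(x$values[, samples, drop = FALSE],
                         structure(as.character(labels[samples]),
                                   names = samples))
  fit <- fit_moderated_t(sub, groups = lv)
  res <- fit$results
  res$is_marker <- res$fdr < fdr_cut
  attr(res, "prior") <- fit$prior
  res
}

#' Validate a subtype signature in an external cohort
#'
#' Restricts the external expression matrix to the marker genes shared
#' by identifier, z-scores each gene, and consensus-clusters the
#' external samples at the given `k`. The returned labels can then be
#' compared against external survival.
#'
#' @param external Genes-by-samples numeric matrix of the external
#'   cohort.
#' @param markers Character vector of marker identifiers; at least 10
#'   must be present in `external`.
#' @param k Number of clusters (default 2).
#' @param reps,subsample_frac,seed Passed to [consensus_cluster()].
#' @return A list with `labels` (named integer vector) and `consensus`
#'   (the `consensus_result`).
#' @export
validate_signature <- function(external, markers, k = 2, reps = 1000,
                               subsample_frac = 0.8, seed = 1) {
  shared <- intersect(markers, rownames(external))
  if (length(shared) < 10) {
    stop("fewer than 10 marker identifiers shared; missing: ",
         paste(utils::head(setdiff(markers, rownames(external)), 20),
               collapse = ", "))
  }
  dropped <- length(markers) - length(shared)
  if (dropped > 0) {
    message(dropped, " marker(s) not present in the external cohort dropped")
  }
  cc <- consensus_cluster(external[shared, , drop = FALSE], k_max = k,
                          reps = reps, subsample_frac = subsample_frac,
                          seed = seed, chosen_k = k)
  list(labels = cc$labels[[as.character(k)]], consensus = cc)
}
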