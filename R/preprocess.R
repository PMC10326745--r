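#' Quantile-normalize an abundance table
#'
#' Each sample's observed values are replaced rank-wise by the mean of
#' the sorted values across samples at that rank, so that after
#' normalization every complete sample carries the identical value
#' distribution. Missing entries are left missing; samples with missing
#' values are normalized by interpolation of the reference quantiles.
#' Rank ties are resolved by averaging the tied ranks' reference values.
#'
#' @param x An [abundance_table()]; the matrix may contain `NA`.
#' @return The normalized `abundance_table`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  n_obs <- colSums(!is.na(x$values))
  if (any(n_obs < 2)) {
    stop("samples with fewer than 2 observed values: ",
         paste(colnames(x$values)[n_obs < 2], collapse = ", "))
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  x$values <- v
  x
}

#' Drop proteins with too much missing data
#'
#' Retains exactly the proteins whose missing fraction across all
#' samples is strictly below `max_missing`.
#'
#' @param x An [abundance_table()].
#' @param max_missing Maximum tolerated missing fraction (default 0.40).
#' @return The filtered `abundance_table`.
#' @export
filter_missing <- function(x, max_missing = 0.40) {
  stopifnot(inherits(x, "abundance_table"))
  frac <- rowMeans(is.na(x$values))
  # complete proteins always survive, so the boundary max_missing = 0
  # means "complete proteins only"
  keep <- frac < max_missing | frac == 0
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' K-nearest-neighbor imputation of missing abundances
#'
#' Each missing entry is replaced by the average of that sample's values
#' over the `k` nearest proteins, where proximity is the mean squared
#' difference over co-observed samples. Neighbors missing in the target
#' sample are skipped in favor of the next-nearest; if no neighbor can
#' supply a value the protein's own observed mean is used. Observed
#' entries are never altered.
#'
#' @param x An [abundance_table()] in which every protein has at least
#'   one observed value.
#' @param k Number of neighbors (default 10, the conventional default of
#'   nearest-neighbor expression imputation).
#' @return The completed `abundance_table` (no missing values).
#' @export
knn_impute <- function(x, k = 10) {
  stopifnot(inherits(x, "abundance_table"))
  v <- x$values
  if (!anyNA(v)) return(x)
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("proteins with no observed values must be filtered first: ",
         paste(rownames(v)[all_missing], collapse = ", "))
  }
  targets <- which(rowSums(is.na(v)) > 0)
  for (i in targets) {
    xi <- v[i, ]
    # mean squared difference over co-observed samples; Inf if none
    sq <- sweep(x$values, 2, xi)^2
    d <- rowMeans(sq, na.rm = TRUE)
    d[i] <- Inf
    d[is.nan(d)] <- Inf
    ord <- order(d)
    ord <- ord[is.finite(d[ord])]
    for (j in which(is.na(xi))) {
      donors <- ord[!is.na(x$values[ord, j])]
      if (length(donors) == 0L) {
        v[i, j] <- mean(xi, na.rm = TRUE)
      } else {
        v[i, j] <- mean(x$values[donors[seq_len(min(k, length(donors)))], j])
      }
    }
  }
  x$values <- v
  x
}

#' Full preprocessing: normalize, filter, impute
#'
#' Applies [quantile_normalize()], [filter_missing()] and [knn_impute()]
#' in that order, mirroring the standard label-free workflow of
#' log2-transformed intensity data.
#'
#' @inheritParams filter_missing
#' @inheritParams knn_impute
#' @return A complete (no `NA`), normalized `abundance_table`.
#' @export
preprocess <- function(x, max_missing = 0.40, k = 10) {
  knn_impute(filter_missing(quantile_normalize(x), max_missing), k)
}
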