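#' All-pairs per-group correlations with difference tests
#'
#' For every unordered pair of proteins, the Pearson correlation is
#' computed separately in the case and in the control samples, each with
#' its exact t-based p-value, and the two coefficients are compared by
#' the Fisher Z-transformation difference test. Within-group p-values
#' and difference p-values are each Benjamini-Hochberg adjusted across
#' all tested pairs. Proteins with zero variance in either group are
#' dropped before pairing and excluded from all denominators.
#'
#' Pairs are stored canonically: proteins are ordered lexicographically
#' and each pair is indexed `ia < ib` into that ordering, so that the
#' result is invariant to the input row order. Correlation matrices are
#' computed in row blocks so that the working memory stays at a small
#' multiple of the final per-pair vectors even for several thousand
#' proteins.
#'
#' @param x A preprocessed [abundance_table()] (no missing values) with
#'   both groups larger than 3 samples.
#' @param groups Length-2 character vector naming the control and the
#'   case group.
#' @param block_size Number of proteins per correlation block.
#' @return A data frame of class `coex_links` with integer columns
#'   `ia`, `ib` and numeric columns `r_case`, `p_case`, `fdr_case`,
#'   `r_ctrl`, `p_ctrl`, `fdr_ctrl`, `z_diff`, `p_diff`, `fdr_diff`.
#'   The lexicographically sorted protein vector is kept in
#'   `attr(, "proteins")`, the group sizes in `attr(, "n_case")` and
#'   `attr(, "n_ctrl")`.
#' @export
all_pair_correlations <- function(x, groups = c("control", "case"),
                                  block_size = 1000L) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("missing values must be imputed first")
  g1 <- group_samples(x, groups[1])
  g2 <- group_samples(x, groups[2])
  if (length(g1) <= 3 || length(g2) <= 3) {
    stop("Fisher Z requires more than 3 samples per group")
  }
  v <- x$values[order(rownames(x$values)), , drop = FALSE]
  sd1 <- apply(v[, g1, drop = FALSE], 1, stats::sd)
  sd2 <- apply(v[, g2, drop = FALSE], 1, stats::sd)
  keep <- sd1 > 0 & sd2 > 0
  if (sum(keep) < 2) stop("fewer than 2 proteins with nonzero variance")
  v <- v[keep, , drop = FALSE]
  proteins <- rownames(v)
  p <- length(proteins)
  n1 <- length(g1)
  n2 <- length(g2)

  # unit-scaled group matrices: correlation blocks become crossproducts
  z1 <- scale_rows_unit(v[, g1, drop = FALSE])
  z2 <- scale_rows_unit(v[, g2, drop = FALSE])

  npair <- p * (p - 1) / 2
  ia <- integer(npair); ib <- integer(npair)
  r1 <- numeric(npair); r2 <- numeric(npair)
  starts <- seq(1L, p, by = block_size)
  pos <- 0L
  for (bi in starts) {
    ri <- bi:min(bi + block_size - 1L, p)
    for (bj in starts[starts >= bi]) {
      rj <- bj:min(bj + block_size - 1L, p)
      c1 <- tcrossprod(z1[ri, , drop = FALSE], z1[rj, , drop = FALSE])
      c2 <- tcrossprod(z2[ri, , drop = FALSE], z2[rj, , drop = FALSE])
      idx <- which(outer(ri, rj, `<`))
      if (!length(idx)) next
      take <- pos + seq_along(idx)
      ia[take] <- ri[row(c1)[idx]]
      ib[take] <- rj[col(c1)[idx]]
      r1[take] <- c2[idx]  # case
      r2[take] <- c1[idx]  # control
      pos <- pos + length(idx)
    }
  }
  o <- order(ia, ib)
  ia <- ia[o]; ib <- ib[o]
  r_case <- pmin(1, pmax(-1, r1[o]))
  r_ctrl <- pmin(1, pmax(-1, r2[o]))

  p_case <- cor_p_from_r(r_case, n2)
  p_ctrl <- cor_p_from_r(r_ctrl, n1)
  cl <- 1 - 1e-15  # keep atanh finite for numerically perfect correlations
  z_diff <- (atanh(pmin(cl, pmax(-cl, r_case))) -
               atanh(pmin(cl, pmax(-cl, r_ctrl)))) /
    sqrt(1 / (n2 - 3) + 1 / (n1 - 3))
  p_diff <- 2 * stats::pnorm(-abs(z_diff))

  links <- data.frame(
    ia = ia, ib = ib,
    r_case = r_case, p_case = p_case,
    fdr_case = stats::p.adjust(p_case, "BH"),
    r_ctrl = r_ctrl, p_ctrl = p_ctrl,
    fdr_ctrl = stats::p.adjust(p_ctrl, "BH"),
    z_diff = z_diff, p_diff = p_diff,
    fdr_diff = stats::p.adjust(p_diff, "BH")
  )
  attr(links, "proteins") <- proteins
  attr(links, "n_case") <- n2
  attr(links, "n_ctrl") <- n1
  class(links) <- c("coex_links", "data.frame")
  links
}

scale_rows_unit <- function(m) {
  m <- m - rowMeans(m)
  m / sqrt(rowSums(m^2))
}

#' Protein identifiers of each link
#' @param links A `coex_links` data frame.
#' @return A data frame with character columns `protein_a`, `protein_b`.
#' @export
link_pairs <- function(links) {
  prot <- attr(links, "proteins")
  data.frame(protein_a = prot[links$ia], protein_b = prot[links$ib],
             stringsAsFactors = FALSE)
}

#' Classify differentially co-expressed links (DCLs)
#'
#' A pair is a co-expressed link when its correlation is strong and
#' significant in at least one group: `|r| > rth` with group FDR below
#' `qth` in the case or in the control samples. Among the co-expressed
#' links the difference p-values are re-adjusted by Benjamini-Hochberg
#' (column `fdr_dcl`), and a co-expressed link is a DCL when in addition
#' `|r_case - r_ctrl| > r_diffth` and `fdr_dcl < q_diffth`. DCLs are
#' classed `gain` (only case-significant), `loss` (only
#' control-significant) or `reversal` (both significant with opposite
#' signs).
#'
#' @param links A `coex_links` data frame from
#'   [all_pair_correlations()].
#' @param rth,qth Within-group correlation magnitude and FDR thresholds.
#' @param r_diffth,q_diffth Correlation-difference magnitude and FDR
#'   thresholds.
#' @return `links` with logical columns `is_coexpressed`, `is_dcl`,
#'   numeric `fdr_dcl` and character `dcl_class` appended.
#' @export
classify_dcl <- function(links, rth = 0.5, qth = 0.1,
                         r_diffth = 0.5, q_diffth = 0.1) {
  sig_case <- abs(links$r_case) > rth & links$fdr_case < qth
  sig_ctrl <- abs(links$r_ctrl) > rth & links$fdr_ctrl < qth
  colink <- sig_case | sig_ctrl
  fdr_dcl <- rep(NA_real_, nrow(links))
  fdr_dcl[colink] <- stats::p.adjust(links$p_diff[colink], "BH")
  is_dcl <- colink & abs(links$r_case - links$r_ctrl) > r_diffth &
    !is.na(fdr_dcl) & fdr_dcl < q_diffth
  cls <- rep(NA_character_, nrow(links))
  cls[is_dcl & sig_case & !sig_ctrl] <- "gain"
  cls[is_dcl & !sig_case & sig_ctrl] <- "loss"
  cls[is_dcl & sig_case & sig_ctrl &
        sign(links$r_case) != sign(links$r_ctrl)] <- "reversal"
  links$is_coexpressed <- colink
  links$fdr_dcl <- fdr_dcl
  links$is_dcl <- is_dcl
  links$dcl_class <- cls
  links
}

#' Differentially co-expressed proteins (DCPs)
#'
#' Tests, per protein, whether it carries more DCLs than expected under
#' a global-rate binomial model: with `rate` the overall fraction of
#' DCLs among the tested links, the protein's DCL count among its own
#' tested links is referred to the inclusive binomial upper tail, and
#' p-values are BH-adjusted across proteins. By default every tested
#' pair counts as a trial; `scope = "coexpressed"` restricts trials and
#' the global rate to the co-expressed links.
#'
#' @param links A classified `coex_links` data frame ([classify_dcl()]).
#' @param qth FDR threshold for the DCP call (default 0.1).
#' @param scope Denominator of the binomial model: `"all"` tested pairs
#'   or only `"coexpressed"` links.
#' @return A data frame with columns `protein`, `n_links_tested`,
#'   `n_dcl`, `p`, `fdr`, `is_dcp`.
#' @export
find_dcps <- function(links, qth = 0.1, scope = c("all", "coexpressed")) {
  scope <- match.arg(scope)
  if (is.null(links$is_dcl)) stop("links must be classified first")
  if (nrow(links) == 0) stop("zero tested links")
  prot <- attr(links, "proteins")
  p <- length(prot)
  tested <- if (scope == "all") rep(TRUE, nrow(links)) else links$is_coexpressed
  n_i <- tabulate(links$ia[tested], p) + tabulate(links$ib[tested], p)
  k_i <- tabulate(links$ia[links$is_dcl], p) +
    tabulate(links$ib[links$is_dcl], p)
  rate <- sum(links$is_dcl) / sum(tested)
  pv <- rep(1, p)
  has <- n_i > 0
  pv[has] <- binomial_tail(k_i[has], n_i[has], rate)
  fdr <- stats::p.adjust(pv, "BH")
  data.frame(protein = prot, n_links_tested = n_i, n_dcl = k_i,
             p = pv, fdr = fdr, is_dcp = fdr < qth,
             stringsAsFactors = FALSE)
}

#' Pathway enrichment of differentially co-expressed links
#'
#' A link belongs to a gene set when both of its proteins are members.
#' Per set, the 2x2 table of DCL status against set membership over all
#' tested links is tested one-sided by Fisher's exact test, with BH
#' adjustment across sets. Sets containing no tested link are skipped
#' with a warning.
#'
#' @param links A classified `coex_links` data frame.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @return A data frame with columns `set_name`, `n_links`, `n_dcl`,
#'   `p`, `fdr` and `dcl_pairs` (semicolon-separated `A-B` pairs).
#' @export
link_pathway_enrichment <- function(links, sets) {
  if (is.null(links$is_dcl)) stop("links must be classified first")
  prot <- attr(links, "proteins")
  total_dcl <- sum(links$is_dcl)
  total <- nrow(links)
  res <- lapply(names(sets), function(nm) {
    mem <- prot %in% sets[[nm]]
    in_set <- mem[links$ia] & mem[links$ib]
    n_links <- sum(in_set)
    if (n_links == 0) return(NULL)
    a <- sum(in_set & links$is_dcl)
    pv <- fisher_exact_enrichment(a, total_dcl - a, n_links - a,
                                  total - n_links - (total_dcl - a),
                                  alternative = "greater")
    pairs <- if (a > 0) {
      sel <- which(in_set & links$is_dcl)
      paste(paste0(prot[links$ia[sel]], "-", prot[links$ib[sel]]),
            collapse = ";")
    } else ""
    data.frame(set_name = nm, n_links = n_links, n_dcl = a, p = pv,
               dcl_pairs = pairs, stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(res, is.null, logical(1))]
  if (length(skipped)) {
    warning("sets without any tested link skipped: ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out[order(out$p), c("set_name", "n_links", "n_dcl", "p", "fdr",
                      "dcl_pairs")]
}

#' Write classified links / DCP results as TSV
#' @param links A classified `coex_links` data frame.
#' @param path Output file.
#' @param dcl_only Write only the DCLs (default) or every tested pair.
#' @export
write_dcl_table <- function(links, path, dcl_only = TRUE) {
  keep <- if (dcl_only) which(links$is_dcl) else seq_len(nrow(links))
  out <- cbind(link_pairs(links)[keep, , drop = FALSE],
               as.data.frame(links)[keep, setdiff(colnames(links),
                                                  c("ia", "ib")),
                                    drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
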