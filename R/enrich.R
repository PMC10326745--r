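#' Read / write gene-set collections in GMT format
#'
#' @param path A tab-delimited GMT file (set name, description,
#'   members...).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis against gene sets
#'
#' One-sided hypergeometric test of a query protein list against each
#' gene set, within a stated universe; sets are intersected with the
#' universe first, and p-values are BH-adjusted across sets. Gene sets
#' are taken flat as provided (no ontology-graph propagation).
#'
#' @param query Character vector of identifiers (a subset of
#'   `universe`; identifiers outside it are dropped with a warning).
#' @param sets Named list of gene sets.
#' @param universe Character vector: the background, typically all
#'   proteins surviving preprocessing.
#' @param min_overlap Minimum overlap for a set to be flagged
#'   significant.
#' @param fdr_cut FDR threshold for the `significant` flag.
#' @return A data frame with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`, `significant`, ordered
#'   by p-value.
#' @export
ora <- function(query, sets, universe, min_overlap = 1, fdr_cut = 0.1) {
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(length(out), " query identifier(s) outside the universe dropped")
  }
  query <- unique(intersect(query, universe))
  if (!length(query)) stop("no query identifier inside the universe")
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (!length(s)) return(NULL)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = length(query),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) stop("no set overlaps the universe")
  res$fdr <- stats::p.adjust(res$p, "BH")
  res$significant <- res$fdr < fdr_cut & res$overlap >= min_overlap
  res[order(res$p), ]
}

#' Compare two enrichment analyses on the same collection
#'
#' Partitions the significantly enriched set names of two analyses into
#' shared and analysis-specific groups.
#'
#' @param a,b Enrichment result data frames from [ora()] computed on
#'   the same gene-set collection.
#' @param alpha FDR threshold defining significance.
#' @return A list with character vectors `shared`, `a_only`, `b_only`.
#' @export
compare_enrichments <- function(a, b, alpha = 0.1) {
  if (!setequal(a$set_name, b$set_name)) {
    stop("the two analyses were not computed on the same collection")
  }
  sa <- a$set_name[a$fdr < alpha]
  sb <- b$set_name[b$fdr < alpha]
  list(shared = sort(intersect(sa, sb)),
       a_only = sort(setdiff(sa, sb)),
       b_only = sort(setdiff(sb, sa)))
}
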