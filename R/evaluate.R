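#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two clusterings of the same items:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Recovery metrics of a synthetic run against the planted truth
#'
#' Convenience evaluators used by the reproducibility script and the
#' test-suite: recall and false-discovery proportion of the planted
#' differentially expressed proteins, recovery of planted module pairs
#' among the DCLs, and edge recall/contamination of the unified
#' network.
#'
#' @param truth The `truth` element of [generate_dataset()].
#' @param de_results A called DE results data frame ([call_de()]).
#' @return `evaluate_de`: list with `recall`, `fdp`, `n_called`.
#'   Subtype-marker proteins outside the planted DE set shift the
#'   case-group mean through the subtype mixture, so they are genuinely
#'   (if mildly) differential; they count neither as hits nor as false
#'   discoveries.
#' @export
evaluate_de <- function(truth, de_results) {
  called <- de_results$protein[de_results$status != "ns"]
  planted <- truth$de_proteins
  ambiguous <- setdiff(truth$marker_proteins, planted)
  scored <- setdiff(called, ambiguous)
  list(recall = if (length(planted)) mean(planted %in% called) else NA_real_,
       fdp = if (length(scored)) mean(!(scored %in% planted)) else 0,
       n_called = length(called))
}

#' @rdname evaluate_de
#' @param links A classified `coex_links` data frame.
#' @return `evaluate_dcl`: list with `module_recall` (fraction of
#'   planted within-module pairs that are DCLs), `n_dcl` and
#'   `background_rate` (DCL rate among non-module pairs).
#' @export
evaluate_dcl <- function(truth, links) {
  prot <- attr(links, "proteins")
  lkey <- pair_key(links$ia, links$ib, length(prot))
  me <- truth$module_edges
  if (is.null(me) || !nrow(me)) {
    return(list(module_recall = NA_real_, n_dcl = sum(links$is_dcl),
                background_rate = mean(links$is_dcl)))
  }
  mkey <- edge_keys(me$protein_a, me$protein_b, prot)
  hit <- match(mkey, lkey)
  module_dcl <- links$is_dcl[hit[!is.na(hit)]]
  bg <- !(lkey %in% mkey[!is.na(mkey)])
  list(module_recall = mean(module_dcl),
       n_dcl = sum(links$is_dcl),
       background_rate = mean(links$is_dcl[bg]))
}

#' @rdname evaluate_de
#' @param net A unified network ([build_unified_network()]).
#' @return `evaluate_unified`: list with `edge_recall` (planted module
#'   edges recovered), `contamination` (fraction of unified edges that
#'   are not planted module edges) and `n_edges`.
#' @export
evaluate_unified <- function(truth, net) {
  me <- truth$module_edges
  if (igraph::ecount(net) == 0) {
    return(list(edge_recall = 0, contamination = 0, n_edges = 0))
  }
  el <- igraph::as_edgelist(net)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  mkey <- if (is.null(me)) character(0) else
    paste(pmin(me$protein_a, me$protein_b),
          pmax(me$protein_a, me$protein_b))
  list(edge_recall = if (length(mkey)) mean(mkey %in% ekey) else NA_real_,
       contamination = mean(!(ekey %in% mkey)),
       n_edges = length(ekey))
}
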