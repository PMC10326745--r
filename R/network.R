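#' Load a protein-protein interaction network
#'
#' Reads a tab-delimited edge list, either in the HIPPIE-style
#' six-column dialect (`geneA, idA, geneB, idB, confidence, evidence`)
#' or as a plain two-column edge list, and returns an undirected simple
#' graph: self-interactions are removed, duplicate and reversed edges
#' collapsed.
#'
#' @param path Edge-list file.
#' @param score_min Optional minimum confidence score (HIPPIE dialect
#'   only); edges below it are dropped.
#' @return An undirected [igraph][igraph::graph] with vertex names.
#' @export
load_ppi <- function(path, score_min = NULL) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty PPI file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  header <- 0L
  if (nf[1] >= 2 && grepl("gene|protein|id", fields[[1]][1],
                          ignore.case = TRUE)) {
    header <- 1L
  }
  body <- fields[seq.int(header + 1L, length(fields))]
  nf <- lengths(body)
  bad <- which(nf != 2L & nf < 5L)
  if (length(bad)) {
    stop("malformed PPI line ", bad[1] + header, ": expected 2 or >= 5 ",
         "tab-separated fields, got ", nf[bad[1]])
  }
  two_col <- all(nf == 2L)
  a <- vapply(body, `[[`, "", 1L)
  b <- vapply(body, `[[`, "", if (two_col) 2L else 3L)
  if (!two_col && !is.null(score_min)) {
    conf <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 5L)))
    keep <- !is.na(conf) & conf >= score_min
    a <- a[keep]; b <- b[keep]
  }
  keep <- a != b  # self-interactions removed
  g <- igraph::simplify(igraph::graph_from_edgelist(
    cbind(a[keep], b[keep]), directed = FALSE))
  if (igraph::vcount(g) == 0) stop("PPI network is empty after filtering")
  g
}

#' Write an interaction network as a HIPPIE-style edge list
#' @param g An undirected igraph.
#' @param path Output file.
#' @export
write_ppi <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(geneA = el[, 1], idA = el[, 1],
                   geneB = el[, 2], idB = el[, 2],
                   confidence = 0.9, evidence = "synthetic")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Local enrichment scan of star subnetworks
#'
#' For every scored protein, its star (the protein plus its direct
#' interaction neighbors, restricted to scored proteins) is scored for
#' enrichment of small differential-expression p-values: with the
#' star's `m` member p-values sorted ascending, the raw score is the
#' minimum over `k` of the binomial upper tail
#' \eqn{P(\mathrm{Bin}(m, p_{(k)}) \ge k)}. The raw score is calibrated
#' into an empirical p-value against `n_perm` random size-`m` member
#' sets drawn with replacement from the global p-value pool, and
#' calibrated p-values are BH-adjusted across centers. Nodes without a
#' p-value are excluded from stars rather than treated as
#' non-significant.
#'
#' @param network An undirected igraph with vertex names.
#' @param de_p Named numeric vector of per-protein p-values.
#' @param n_perm Number of calibration draws (default 10000).
#' @param seed Seed for the calibration draws.
#' @param share_null Reuse one null score distribution per star size
#'   (the null depends on the star only through its size); set to
#'   `FALSE` to draw an independent null per center.
#' @param centers Optional subset of node names to scan (default: every
#'   scored node); the p-value pool always covers all scored nodes.
#' @return An object of class `lean_result`: a data frame with columns
#'   `center`, `size`, `lean_score`, `lean_p`, `lean_fdr`, plus the star
#'   memberships in `attr(, "members")`.
#' @export
lean_scan <- function(network, de_p, n_perm = 10000, seed = 1,
                      share_null = TRUE, centers = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse calibration")
  scored <- intersect(igraph::V(network)$name, names(de_p))
  if (!length(scored)) stop("no network node carries a p-value")
  pool <- unname(de_p[scored])
  scan_set <- scored
  if (!is.null(centers)) {
    scan_set <- intersect(scored, centers)
    if (!length(scan_set)) stop("no requested center carries a p-value")
  }
  nbrs <- igraph::adjacent_vertices(network, scan_set)
  members <- lapply(seq_along(scan_set), function(i) {
    union(scan_set[i], intersect(nbrs[[i]]$name, scored))
  })
  names(members) <- scan_set
  sizes <- lengths(members)
  score1 <- function(ps) {
    ps <- sort(ps)
    m <- length(ps)
    min(stats::pbinom(seq_len(m) - 1L, m, ps, lower.tail = FALSE))
  }
  obs <- vapply(members, function(mem) score1(de_p[mem]), numeric(1))

  set.seed(seed)
  lean_p <- numeric(length(scan_set))
  if (share_null) {
    for (m in sort(unique(sizes))) {
      null <- null_lean_scores(pool, m, n_perm)
      idx <- which(sizes == m)
      cnt <- findInterval(obs[idx], sort(null))
      lean_p[idx] <- (cnt + 1) / (n_perm + 1)
    }
  } else {
    for (i in seq_along(scan_set)) {
      null <- null_lean_scores(pool, sizes[i], n_perm)
      lean_p[i] <- (sum(null <= obs[i]) + 1) / (n_perm + 1)
    }
  }
  res <- data.frame(center = scan_set, size = sizes,
                    lean_score = obs, lean_p = lean_p,
                    lean_fdr = stats::p.adjust(lean_p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "members") <- members
  class(res) <- c("lean_result", "data.frame")
  res
}

# null raw scores for stars of size m: rows are random member sets
# drawn with replacement from the global p-value pool
null_lean_scores <- function(pool, m, n_perm) {
  draws <- matrix(pool[sample.int(length(pool), n_perm * m, replace = TRUE)],
                  n_perm, m)
  if (m > 1L) {
    draws <- t(apply(draws, 1L, sort))
  }
  tails <- stats::pbinom(rep(seq_len(m) - 1L, each = n_perm), m, draws,
                         lower.tail = FALSE)
  dim(tails) <- c(n_perm, m)
  if (m == 1L) tails[, 1] else do.call(pmin, asplit(tails, 2L))
}

#' Filter significant stars by differential co-expression enrichment
#'
#' Among the stars significant in the local DE scan
#' (`lean_fdr < lean_fdr_cut`), each star's induced interaction edges
#' are tested for enrichment of DCLs by a one-sided Fisher's exact
#' test, comparing DCL versus non-DCL status of tested pairs inside the
#' star against the background outside it. P-values are Holm-adjusted
#' across the significant stars and stars with adjusted p below `alpha`
#' are kept. Stars without a single tested edge are excluded with a
#' warning.
#'
#' @param stars A `lean_result` from [lean_scan()].
#' @param network The interaction network the stars came from.
#' @param links A classified `coex_links` data frame.
#' @param alpha Holm-adjusted significance cut (default 0.1).
#' @param lean_fdr_cut DE-scan FDR defining the tested stars.
#' @param background Contingency background: all `"tested_pairs"`
#'   outside the star (default) or only the network's `"ppi_edges"`.
#' @return The subset of significant stars with columns `dc_fisher_p`,
#'   `dc_holm_p` and logical `kept` appended.
#' @export
filter_stars_by_dc <- function(stars, network, links, alpha = 0.1,
                               lean_fdr_cut = 0.1,
                               background = c("tested_pairs", "ppi_edges")) {
  background <- match.arg(background)
  if (is.null(links$is_dcl)) stop("links must be classified first")
  sig <- stars[stars$lean_fdr < lean_fdr_cut, , drop = FALSE]
  members <- attr(stars, "members")
  if (!nrow(sig)) {
    sig$dc_fisher_p <- numeric(0)
    sig$dc_holm_p <- numeric(0)
    sig$kept <- logical(0)
    attr(sig, "members") <- members
    return(sig)
  }
  prot <- attr(links, "proteins")
  lkey <- pair_key(links$ia, links$ib, length(prot))
  if (background == "tested_pairs") {
    total_tested <- nrow(links)
    total_dcl <- sum(links$is_dcl)
  } else {
    el <- igraph::as_edgelist(network)
    ek <- edge_keys(el[, 1], el[, 2], prot)
    hit <- match(ek, lkey)
    total_tested <- sum(!is.na(hit))
    total_dcl <- sum(links$is_dcl[hit[!is.na(hit)]])
  }
  counts <- t(vapply(sig$center, function(ctr) {
    mem <- members[[ctr]]
    sub <- igraph::induced_subgraph(network, intersect(mem, igraph::V(network)$name))
    el <- igraph::as_edgelist(sub)
    if (!nrow(el)) return(c(0, 0))
    hit <- match(edge_keys(el[, 1], el[, 2], prot), lkey)
    hit <- hit[!is.na(hit)]
    c(length(hit), sum(links$is_dcl[hit]))
  }, numeric(2)))
  tested_in <- counts[, 1]
  dcl_in <- counts[, 2]
  no_edge <- tested_in == 0
  if (any(no_edge)) {
    warning(sum(no_edge), " significant star(s) without tested edges excluded")
  }
  sig <- sig[!no_edge, , drop = FALSE]
  tested_in <- tested_in[!no_edge]
  dcl_in <- dcl_in[!no_edge]
  pv <- mapply(function(a, t_in) {
    fisher_exact_enrichment(a, total_dcl - a, t_in - a,
                            (total_tested - t_in) - (total_dcl - a),
                            alternative = "greater")
  }, dcl_in, tested_in)
  sig$dc_fisher_p <- as.numeric(pv)
  sig$dc_holm_p <- stats::p.adjust(pv, "holm")
  sig$kept <- sig$dc_holm_p < alpha
  attr(sig, "members") <- members
  class(sig) <- c("lean_result", "data.frame")
  sig
}

# canonical numeric key of an unordered index pair
pair_key <- function(i, j, p) {
  (pmin(i, j) - 1) * p + pmax(i, j)
}

edge_keys <- function(a, b, prot) {
  i <- match(a, prot)
  j <- match(b, prot)
  k <- pair_key(i, j, length(prot))
  k[is.na(i) | is.na(j)] <- NA
  k
}

#' Merge doubly filtered stars into the unified network
#'
#' Within each retained star, interaction edges that are not DCLs are
#' removed; the maximum connected component of what remains (most
#' nodes, ties broken by most edges, then by the lexicographically
#' smallest node set) is kept, and the components of all stars are
#' merged by set union. Every edge of the result is both an interaction
#' edge and a DCL.
#'
#' @param stars The filtered stars from [filter_stars_by_dc()] (only
#'   rows with `kept == TRUE` contribute).
#' @param network The interaction network.
#' @param links A classified `coex_links` data frame.
#' @return An undirected igraph whose edges carry the DCL statistics
#'   (`r_case`, `r_ctrl`, `z_diff`, `fdr_dcl`, `dcl_class`).
#' @export
build_unified_network <- function(stars, network, links) {
  if (is.null(links$is_dcl)) stop("links must be classified first")
  members <- attr(stars, "members")
  keep <- if (is.null(stars$kept)) rep(TRUE, nrow(stars)) else stars$kept
  prot <- attr(links, "proteins")
  lkey <- pair_key(links$ia, links$ib, length(prot))
  all_edges <- NULL
  for (ctr in stars$center[keep]) {
    mem <- intersect(members[[ctr]], igraph::V(network)$name)
    sub <- igraph::induced_subgraph(network, mem)
    el <- igraph::as_edgelist(sub)
    if (!nrow(el)) next
    hit <- match(edge_keys(el[, 1], el[, 2], prot), lkey)
    dcl <- !is.na(hit) & links$is_dcl[hit]
    el <- el[dcl, , drop = FALSE]
    if (!nrow(el)) next
    comp_el <- max_component_edges(el)
    all_edges <- rbind(all_edges, comp_el)
  }
  if (is.null(all_edges)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    a <- pmin(all_edges[, 1], all_edges[, 2])
    b <- pmax(all_edges[, 1], all_edges[, 2])
    uniq <- !duplicated(paste(a, b))
    g <- igraph::graph_from_edgelist(cbind(a[uniq], b[uniq]),
                                     directed = FALSE)
    hit <- match(edge_keys(a[uniq], b[uniq], prot), lkey)
    for (col in c("r_case", "r_ctrl", "z_diff", "fdr_dcl", "dcl_class")) {
      g <- igraph::set_edge_attr(g, col, value = links[[col]][hit])
    }
  }
  g$unified <- TRUE
  g
}

# edge rows of the largest connected component; ties by node count,
# then edge count, then the lexicographically smallest sorted node set
max_component_edges <- function(el) {
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  cmp <- igraph::components(g)
  stats_per <- lapply(seq_len(cmp$no), function(ci) {
    nodes <- igraph::V(g)$name[cmp$membership == ci]
    nedge <- sum(apply(el, 1, function(e) all(e %in% nodes)))
    list(nodes = sort(nodes), n = length(nodes), e = nedge)
  })
  ord <- order(-vapply(stats_per, `[[`, 0, "n"),
               -vapply(stats_per, `[[`, 0, "e"),
               vapply(stats_per, function(s) paste(s$nodes, collapse = ","),
                      ""))
  best <- stats_per[[ord[1]]]$nodes
  el[apply(el, 1, function(e) all(e %in% best)), , drop = FALSE]
}

#' Annotate unified-network nodes
#'
#' Flags nodes by exact identifier match against external gene lists
#' (for example disease genes and druggable targets) and optionally
#' attaches differential-expression status and DCP flags.
#'
#' @param net A unified network from [build_unified_network()].
#' @param disease_genes,druggable Character vectors of identifiers.
#' @param de_results Optional DE results data frame (with `status`).
#' @param dcps Optional DCP results data frame ([find_dcps()]).
#' @return The annotated igraph; overlap counts are reported via
#'   `message()`.
#' @export
annotate_nodes <- function(net, disease_genes = character(),
                           druggable = character(),
                           de_results = NULL, dcps = NULL) {
  if (igraph::vcount(net) == 0) return(net)
  nm <- igraph::V(net)$name
  net <- igraph::set_vertex_attr(net, "disease_gene",
                                 value = nm %in% disease_genes)
  net <- igraph::set_vertex_attr(net, "druggable",
                                 value = nm %in% druggable)
  if (!is.null(de_results)) {
    net <- igraph::set_vertex_attr(
      net, "de_status",
      value = de_results$status[match(nm, de_results$protein)])
  }
  if (!is.null(dcps)) {
    net <- igraph::set_vertex_attr(
      net, "dcp", value = dcps$is_dcp[match(nm, dcps$protein)])
  }
  message(sprintf("annotated %d nodes: %d disease genes, %d druggable",
                  length(nm), sum(nm %in% disease_genes),
                  sum(nm %in% druggable)))
  net
}

#' Extract the subnetwork around a gene set
#'
#' Returns the induced subgraph of the unified network on the given
#' genes, augmented with shortest-path linker nodes (at most
#' `max_linkers` intermediate nodes per gene pair) that connect set
#' members lying in different components.
#'
#' @param net A unified network.
#' @param genes Identifiers of interest.
#' @param max_linkers Maximum number of intermediate nodes per
#'   connecting path.
#' @return An igraph with a logical vertex attribute `linker`; empty
#'   (with a warning) when no gene is present in the network.
#' @export
extract_geneset_subnetwork <- function(net, genes, max_linkers = 2) {
  if (!length(genes)) stop("genes must be nonempty")
  present <- intersect(genes, igraph::V(net)$name)
  if (!length(present)) {
    warning("no gene of the set is present in the network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  nodes <- present
  if (length(present) > 1) {
    for (i in seq_len(length(present) - 1L)) {
      sp <- igraph::shortest_paths(net, from = present[i],
                                   to = present[(i + 1):length(present)],
                                   mode = "all")$vpath
      for (path in sp) {
        if (length(path) >= 2 && length(path) - 2L <= max_linkers) {
          nodes <- union(nodes, names(path))
        }
      }
    }
  }
  sub <- igraph::induced_subgraph(net, nodes)
  igraph::set_vertex_attr(sub, "linker",
                          value = !(igraph::V(sub)$name %in% present))
}

#' Write a network as an annotated edge-list TSV and as GraphML
#' @param net An igraph.
#' @param path Output TSV path; a `.graphml` twin is written alongside.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                   stringsAsFactors = FALSE)
  for (attr_name in igraph::edge_attr_names(net)) {
    df[[attr_name]] <- igraph::edge_attr(net, attr_name)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  igraph::write_graph(net, sub("\\.tsv$", ".graphml", path),
                      format = "graphml")
  invisible(path)
}
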