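test_that("PPI loading canonicalizes the graph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\tidA\tgeneB\tidB\tconfidence\tevidence",
               "A\t1\tB\t2\t0.9\texp",
               "B\t2\tA\t1\t0.8\texp",
               "A\t1\tA\t1\t0.9\texp",
               "C\t3\tD\t4\t0.2\texp",
               "B\t2\tC\t3\t0.7\texp"), f)
  g <- load_ppi(f)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)  # A-B deduped, A-A dropped
  expect_false(any(igraph::which_loop(g)))

  g2 <- load_ppi(f, score_min = 0.5)
  expect_equal(igraph::ecount(g2), 2)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), f2)
  expect_equal(igraph::ecount(load_ppi(f2)), 2)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "broken_line_without_tabs", "C\tD"), f3)
  expect_error(load_ppi(f3), "line 2")
})

test_that("the local star score is the minimum binomial order tail", {
  g <- igraph::graph_from_edgelist(
    cbind(c("ctr", "ctr"), c("n1", "n2")), directed = FALSE)
  de_p <- c(ctr = 0.001, n1 = 0.5, n2 = 0.9)
  res <- lean_scan(g, de_p, n_perm = 200, seed = 1)
  i <- which(res$center == "ctr")
  expect_equal(res$size[i], 3)
  # min over k of P(Bin(3, p_(k)) >= k): k = 1 wins
  expect_equal(res$lean_score[i], 1 - 0.999^3, tolerance = 1e-12)

  # an isolated scored node scores its own p-value
  g2 <- igraph::add_vertices(g, 1, name = "solo")
  res2 <- lean_scan(g2, c(de_p, solo = 0.37), n_perm = 200, seed = 1)
  expect_equal(res2$lean_score[res2$center == "solo"], 0.37)
})

test_that("a flat p-value landscape yields no significant star", {
  set.seed(2)
  g <- igraph::sample_pa(60, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("P%03d", 1:60)
  de_p <- structure(rep(1, 60), names = igraph::V(g)$name)
  res <- lean_scan(g, de_p, n_perm = 300, seed = 3)
  expect_true(all(res$lean_fdr > 0.5))
})

test_that("unscored nodes are excluded from stars", {
  g <- igraph::graph_from_edgelist(
    cbind(c("a", "a", "a"), c("b", "c", "d")), directed = FALSE)
  de_p <- c(a = 0.5, b = 0.5, c = 0.5)  # d carries no p-value
  res <- lean_scan(g, de_p, n_perm = 100, seed = 1)
  expect_equal(sort(attr(res, "members")[["a"]]), c("a", "b", "c"))
  expect_false("d" %in% res$center)
})

test_that("star DC filtering keeps only DCL-enriched stars", {
  # star edges 8/10 DCL against a 100/1000 background
  prot <- sprintf("P%03d", 1:40)
  star_pairs <- cbind(1L, 2L:11L)
  bg <- t(combn(12L:40L, 2))
  df <- data.frame(ia = c(star_pairs[, 1], bg[, 1]),
                   ib = c(star_pairs[, 2], bg[, 2]))
  df$is_dcl <- FALSE
  df$is_dcl[1:8] <- TRUE                       # 8 of 10 star edges
  df$is_dcl[10 + seq_len(100)] <- TRUE         # 100 background DCLs
  df$is_coexpressed <- df$is_dcl
  links <- make_links(df, prot)

  g <- igraph::graph_from_edgelist(
    cbind(prot[star_pairs[, 1]], prot[star_pairs[, 2]]),
    directed = FALSE)
  stars <- data.frame(center = "P001", size = 11L, lean_score = 1e-4,
                      lean_p = 1e-4, lean_fdr = 1e-3)
  attr(stars, "members") <- list(P001 = prot[1:11])
  class(stars) <- c("lean_result", "data.frame")

  kept <- filter_stars_by_dc(stars, g, links, alpha = 0.1)
  n_out <- nrow(links) - 10
  dcl_out <- sum(links$is_dcl) - 8
  expect_equal(kept$dc_fisher_p,
               fisher_exact_enrichment(8, dcl_out, 2, n_out - dcl_out))
  expect_true(kept$kept)

  # no DCL in the star: p = 1, filtered out
  links2 <- links
  links2$is_dcl[1:8] <- FALSE
  kept2 <- filter_stars_by_dc(stars, g, links2, alpha = 0.1)
  expect_equal(kept2$dc_fisher_p, 1)
  expect_false(kept2$kept)
})

test_that("unified network construction prunes, components and merges", {
  prot <- c("a", "b", "c", "d", "e")
  df <- data.frame(ia = c(1L, 1L, 2L, 4L), ib = c(2L, 3L, 3L, 5L),
                   r_case = 0.9, r_ctrl = 0, z_diff = 4, fdr_dcl = 0.01,
                   dcl_class = "gain")
  df$is_dcl <- c(TRUE, FALSE, FALSE, TRUE)
  links <- make_links(df, prot)
  g <- igraph::graph_from_edgelist(
    cbind(c("a", "a", "b", "d"), c("b", "c", "c", "e")),
    directed = FALSE)

  star1 <- data.frame(center = "a", size = 3, lean_score = 1e-3,
                      lean_p = 1e-3, lean_fdr = 1e-3, kept = TRUE)
  attr(star1, "members") <- list(a = c("a", "b", "c"),
                                 b = c("a", "b", "c"),
                                 d = c("d", "e"))
  class(star1) <- c("lean_result", "data.frame")
  # star {a-b DCL, a-c non-DCL} contributes only the component {a, b}
  net <- build_unified_network(star1, g, links)
  expect_setequal(igraph::V(net)$name, c("a", "b"))
  expect_equal(igraph::ecount(net), 1)

  # two stars sharing the DCL edge (a, b): the union holds it once;
  # star order does not matter
  stars2 <- rbind(star1, data.frame(center = "b", size = 3,
                                    lean_score = 1e-3, lean_p = 1e-3,
                                    lean_fdr = 1e-3, kept = TRUE))
  attr(stars2, "members") <- attr(star1, "members")
  class(stars2) <- c("lean_result", "data.frame")
  net2 <- build_unified_network(stars2, g, links)
  expect_equal(igraph::ecount(net2), 1)
  stars_rev <- stars2[2:1, ]
  attr(stars_rev, "members") <- attr(star1, "members")
  class(stars_rev) <- c("lean_result", "data.frame")
  net_rev <- build_unified_network(stars_rev, g, links)
  expect_setequal(igraph::V(net_rev)$name, igraph::V(net2)$name)

  # no DCL edges anywhere: empty unified network
  links3 <- links
  links3$is_dcl[] <- FALSE
  expect_equal(igraph::ecount(build_unified_network(star1, g, links3)), 0)

  # every unified edge is both a PPI edge and a DCL
  el <- igraph::as_edgelist(net2)
  expect_true(all(paste(el[, 1], el[, 2]) %in% c("a b", "b a")))
})

test_that("node annotation counts exact identifier overlaps", {
  g <- igraph::graph_from_edgelist(cbind(c("a", "b"), c("b", "c")),
                                   directed = FALSE)
  g$unified <- TRUE
  expect_message(net <- annotate_nodes(g, disease_genes = c("a", "z"),
                                       druggable = character()),
                 "1 disease genes")
  expect_equal(sum(igraph::V(net)$disease_gene), 1)
  expect_equal(sum(igraph::V(net)$druggable), 0)
  net2 <- suppressMessages(
    annotate_nodes(g, disease_genes = c("a", "b", "c")))
  expect_true(all(igraph::V(net2)$disease_gene))
})

test_that("gene-set subnetwork extraction adds shortest-path linkers", {
  g <- igraph::graph_from_edgelist(
    cbind(c("a", "x", "b", "q"), c("x", "b", "q", "r")),
    directed = FALSE)
  one <- extract_geneset_subnetwork(g, "a")
  expect_equal(igraph::V(one)$name, "a")

  # two set members joined by one intermediate node
  sub <- extract_geneset_subnetwork(g, c("a", "b"), max_linkers = 1)
  expect_setequal(igraph::V(sub)$name, c("a", "b", "x"))
  expect_true(igraph::V(sub)$linker[igraph::V(sub)$name == "x"])

  expect_warning(empty <- extract_geneset_subnetwork(g, "nope"),
                 "no gene")
  expect_equal(igraph::vcount(empty), 0)
})
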