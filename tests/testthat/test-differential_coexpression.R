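test_that("all pairs are emitted once, in canonical order", {
  x <- make_table(p = 4, n1 = 5, n2 = 5, seed = 1)
  links <- all_pair_correlations(x)
  expect_equal(nrow(links), 6)
  expect_true(all(links$ia < links$ib))
  prot <- attr(links, "proteins")
  expect_equal(prot, sort(rownames(x$values)))

  # shuffling the input row order changes nothing
  y <- x
  perm <- c(3, 1, 4, 2)
  y$values <- y$values[perm, ]
  links2 <- all_pair_correlations(y)
  expect_equal(as.data.frame(links2), as.data.frame(links))
})

test_that("correlations match a naive double-loop oracle", {
  x <- make_table(p = 50, n1 = 8, n2 = 6, seed = 12)
  links <- all_pair_correlations(x)
  v <- x$values[order(rownames(x$values)), ]
  cs <- colnames(v)[x$design[colnames(v)] == "case"]
  ct <- setdiff(colnames(v), cs)
  idx <- sample(nrow(links), 200)
  for (r in idx) {
    a <- links$ia[r]; b <- links$ib[r]
    expect_equal(links$r_case[r], cor(v[a, cs], v[b, cs]),
                 tolerance = 1e-12)
    expect_equal(links$r_ctrl[r], cor(v[a, ct], v[b, ct]),
                 tolerance = 1e-12)
    pw <- pearson_with_p(v[a, cs], v[b, cs])
    expect_equal(links$p_case[r], pw$p, tolerance = 1e-12)
    fz <- fisher_z_diff_test(links$r_case[r], length(cs),
                             links$r_ctrl[r], length(ct))
    expect_equal(links$z_diff[r], fz$z, tolerance = 1e-9)
  }
})

test_that("block partitioning does not change the result", {
  x <- make_table(p = 37, n1 = 6, n2 = 6, seed = 13)
  a <- all_pair_correlations(x, block_size = 7L)
  b <- all_pair_correlations(x, block_size = 1000L)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("duplicated proteins give perfect correlations", {
  x <- make_table(p = 5, n1 = 6, n2 = 6, seed = 2)
  x$values[2, ] <- x$values[1, ]
  links <- all_pair_correlations(x)
  i <- which(links$ia == 1 & links$ib == 2)
  expect_equal(links$r_case[i], 1)
  expect_equal(links$r_ctrl[i], 1)
})

test_that("zero-variance proteins are dropped from the denominator", {
  x <- make_table(p = 6, n1 = 6, n2 = 6, seed = 3)
  x$values[4, 1:6] <- 7  # constant in the case group
  links <- all_pair_correlations(x)
  expect_equal(nrow(links), choose(5, 2))
  expect_false("P004" %in% attr(links, "proteins"))
})

test_that("DCL classification reproduces the published link patterns", {
  # gain: strong tumor-only correlation; loss: control-only; the
  # correlation values mirror the published EGFR-SRC / PTPN6-STAT3 pairs
  df <- data.frame(
    ia = c(1L, 1L, 2L), ib = c(2L, 3L, 3L),
    r_case = c(0.70, -0.24, 0.80), p_case = c(1e-4, 0.3, 1e-5),
    fdr_case = c(3.9e-3, 0.60, 0.01),
    r_ctrl = c(-0.19, 0.84, 0.80), p_ctrl = c(0.4, 1e-6, 1e-5),
    fdr_ctrl = c(0.72, 5.3e-4, 0.01),
    z_diff = c(3.5, -4.3, 0), p_diff = c(4e-4, 2e-5, 1),
    fdr_diff = c(1e-3, 1e-4, 1))
  links <- make_links(df, c("EGFR", "SRC", "STAT3"))
  got <- classify_dcl(links)
  expect_equal(got$is_dcl, c(TRUE, TRUE, FALSE))
  expect_equal(got$dcl_class, c("gain", "loss", NA))
  # equal strong correlations in both groups: condition (2) fails
  expect_false(got$is_dcl[3])
})

test_that("DCP detection follows the global-rate binomial model", {
  # protein 1 participates in 10 tested links of which 5 are DCLs,
  # against a global DCL rate forced to ~0.1
  n_extra <- 445
  df <- data.frame(ia = c(rep(1L, 10), rep(2:30, length.out = n_extra)),
                   ib = c(2:11, rep(31:60, length.out = n_extra)))
  df$ib <- pmax(df$ib, df$ia + 1L)
  df <- df[!duplicated(df[c("ia", "ib")]), ]
  df$is_dcl <- FALSE
  df$is_dcl[1:5] <- TRUE
  extra_dcl <- which(df$ia > 1)[seq_len(round(0.1 * nrow(df)) - 5)]
  df$is_dcl[extra_dcl] <- TRUE
  df$is_coexpressed <- TRUE
  links <- make_links(df, sprintf("P%03d", 1:60))
  rate <- mean(links$is_dcl)
  got <- find_dcps(links)
  i <- which(got$protein == "P001")
  expect_equal(got$n_links_tested[i], 10)
  expect_equal(got$n_dcl[i], 5)
  expect_equal(got$p[i], binomial_tail(5, 10, rate))
  expect_equal(got$p[got$n_dcl == 0], rep(1, sum(got$n_dcl == 0)))
})

test_that("a saturated DCL rate leaves no detectable hub", {
  df <- data.frame(ia = rep(1L, 5), ib = 2:6,
                   is_dcl = TRUE, is_coexpressed = TRUE)
  links <- make_links(df, sprintf("P%03d", 1:6))
  got <- find_dcps(links)
  expect_equal(got$p, rep(1, 6))
  expect_false(any(got$is_dcp))
})

test_that("a planted module outranks decoy sets in link enrichment", {
  set.seed(21)
  cfg <- synthetic_config(n_proteins = 80, module_size = 8,
                          missing_fraction = 0, n_subtypes = 1,
                          de_fraction = 0, seed = 21)
  ds <- generate_dataset(cfg)
  links <- classify_dcl(all_pair_correlations(preprocess(ds$abundance)))
  mem <- sort(names(ds$truth$module_assignments))
  sets <- c(list(planted = mem),
            lapply(setNames(1:20, paste0("decoy", 1:20)), function(i) {
              sample(rownames(ds$abundance$values), 8)
            }))
  enr <- link_pathway_enrichment(links, sets)
  expect_equal(enr$set_name[1], "planted")
  expect_lt(enr$p[1], 0.01)
})

test_that("degenerate enrichment margins give p = 1", {
  df <- data.frame(ia = c(1L, 1L, 2L), ib = c(2L, 3L, 3L),
                   is_dcl = TRUE, is_coexpressed = TRUE)
  links <- make_links(df, c("A", "B", "C"))
  expect_warning(
    enr <- link_pathway_enrichment(links, list(all = c("A", "B", "C"),
                                               off = c("X", "Y"))),
    "skipped")
  expect_equal(enr$p, 1)
})
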