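test_that("perfectly separable duplicated samples give a 0/1 consensus", {
  # the two groups differ with mixed signs per protein, as a correlation
  # distance on z-scored features requires
  set.seed(5)
  a <- rnorm(40)
  b <- a + sample(c(-6, 6), 40, replace = TRUE)
  v <- cbind(a, a, a, a, a, a, b, b, b, b, b, b) + rnorm(40 * 12, sd = 1e-3)
  dimnames(v) <- list(sprintf("P%02d", 1:40), sprintf("S%02d", 1:12))
  cc <- consensus_cluster(v, k_max = 2, reps = 100, seed = 1)
  cons <- cc$consensus[["2"]]
  expect_true(all(cons %in% c(0, 1)))
  truth <- rep(1:2, each = 6)
  expect_equal(adjusted_rand_index(cc$labels[["2"]], truth), 1)
})

test_that("consensus clustering is deterministic given its seed", {
  v <- matrix(rnorm(30 * 14), 30,
              dimnames = list(sprintf("P%02d", 1:30),
                              sprintf("S%02d", 1:14)))
  a <- consensus_cluster(v, k_max = 3, reps = 60, seed = 9)
  b <- consensus_cluster(v, k_max = 3, reps = 60, seed = 9)
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$labels, b$labels)
})

test_that("two well-separated Gaussian blobs are recovered at k = 2", {
  set.seed(6)
  n_half <- 15
  v <- cbind(matrix(rnorm(50 * n_half), 50),
             matrix(rnorm(50 * n_half), 50) +
               sample(c(-2, 2), 50, replace = TRUE))
  dimnames(v) <- list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:30))
  cc <- consensus_cluster(v, k_max = 3, reps = 100, seed = 2)
  truth <- rep(1:2, each = n_half)
  expect_equal(adjusted_rand_index(cc$labels[["2"]], truth), 1)
})

test_that("the package ARI agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 1, 4, 3, 5)), 1,
               tolerance = 1e-12)
})

test_that("subtype markers require a sane two-group design", {
  x <- make_table(p = 30, n1 = 10, n2 = 4, seed = 10)
  cs <- colnames(x$values)[x$design == "case"]
  expect_error(subtype_markers(x, structure(rep(1, 10), names = cs)),
               "two subtype labels")
  expect_error(subtype_markers(x, structure(c(1, rep(2, 9)), names = cs)),
               "at least 2 samples")
})

test_that("planted subtype markers are recovered and permutation kills them", {
  cfg <- synthetic_config(n_proteins = 400, subtype_effect = 2,
                          n_markers = 40, missing_fraction = 0, seed = 13)
  ds <- generate_dataset(cfg)
  pre <- preprocess(ds$abundance)
  labs <- ds$truth$subtype_labels
  mk <- subtype_markers(pre, labs, fdr_cut = 0.001)
  recall <- mean(ds$truth$marker_proteins %in% mk$protein[mk$is_marker])
  expect_gte(recall, 0.9)

  set.seed(99)
  shuf <- structure(sample(labs), names = names(labs))
  mk2 <- subtype_markers(pre, shuf, fdr_cut = 0.001)
  expect_lte(sum(mk2$is_marker), 2)
})

test_that("self-validation of a signature reproduces the discovery labels", {
  cfg <- synthetic_config(n_proteins = 300, subtype_effect = 2,
                          missing_fraction = 0, seed = 14)
  ds <- generate_dataset(cfg)
  cs <- names(ds$abundance$design)[ds$abundance$design == "case"]
  val <- validate_signature(ds$abundance$values[, cs],
                            ds$truth$marker_proteins, k = 2, reps = 100,
                            seed = 3)
  expect_equal(adjusted_rand_index(val$labels, ds$truth$subtype_labels), 1)
  expect_error(validate_signature(ds$abundance$values[1:5, cs],
                                  ds$truth$marker_proteins),
               "fewer than 10")
})

test_that("the product-limit estimator handles censoring", {
  tab <- survival_table(paste0("s", 1:3), c(1, 2, 3), c(1, 1, 1), "g")
  km <- km_curve(tab)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  cens <- survival_table(paste0("s", 1:4), c(1, 2, 3, 4), 0, "g")
  expect_true(all(km_curve(cens)$surv == 1))

  one <- km_curve(survival_table("s1", 5, 1, "g"))
  expect_equal(one$time, 5)
  expect_equal(one$surv, 0)

  expect_error(survival_table("s1", -1, 1, "g"), "negative")
})

test_that("the log-rank test matches the hand-computed risk table", {
  tab <- survival_table(paste0("s", 1:6), c(1, 2, 3, 4, 5, 6), 1,
                        rep(c("A", "B"), each = 3))
  lr <- logrank_test(tab)
  # O_A = 3, E_A = 0.5 + 0.4 + 0.25, V = 0.25 + 0.24 + 0.1875
  expect_equal(lr$chi2, (3 - 1.15)^2 / 0.6775, tolerance = 1e-10)
  expect_equal(lr$chi2, 5.05, tolerance = 1e-3)
  expect_equal(lr$p, 0.025, tolerance = 0.02)

  # symmetry under relabeling and invariance to time rescaling
  tab2 <- tab
  tab2$group <- rev(tab$group)
  expect_equal(logrank_test(tab2)$chi2, lr$chi2)
  tab3 <- tab
  tab3$time <- tab$time * 365.25
  expect_equal(logrank_test(tab3)$chi2, lr$chi2)

  same <- survival_table(paste0("s", 1:6), rep(c(1, 3, 7), 2),
                         rep(c(1, 0, 1), 2), rep(c("A", "B"), each = 3))
  expect_equal(logrank_test(same)$chi2, 0, tolerance = 1e-12)
  expect_equal(logrank_test(same)$p, 1)

  none <- survival_table(paste0("s", 1:4), 1:4, 0,
                         rep(c("A", "B"), 2))
  expect_error(logrank_test(none), "no events")
})
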