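#' Pipeline configuration
#'
#' Collects the file paths, thresholds, repetition counts and seed of a
#' full pipeline run. The threshold defaults are the analysis settings
#' of the targeted study design: 40% missingness filter, DE at FDR 0.1
#' with fold change 1.5, DCL thresholds 0.5/0.1 on both the correlation
#' and the correlation difference, local-scan FDR 0.1, star filter at
#' Holm-adjusted 0.1, subtype markers at FDR 0.001, 10000 calibration
#' permutations and 1000 consensus subsamples up to k = 6.
#'
#' @param abundance,design,ppi,gmt,survival,mrna,mrna_survival,truth
#'   Input file paths (set by [simulate_dataset()] for synthetic runs;
#'   `truth`, `mrna` and `mrna_survival` are optional).
#' @param out_dir Output directory.
#' @param max_missing,de_fdr,de_fc,dcl_rth,dcl_qth,dcl_r_diffth,dcl_q_diffth,lean_fdr,star_alpha,subtype_fdr
#'   Thresholds (see above).
#' @param knn_k Neighbors for imputation.
#' @param lean_perm,consensus_reps,k_max Repetition counts.
#' @param seed Seed used by every randomized stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance, design, ppi, gmt = NULL,
                            survival = NULL, mrna = NULL,
                            mrna_survival = NULL, truth = NULL,
                            out_dir = "dconet_out",
                            max_missing = 0.40, knn_k = 10,
                            de_fdr = 0.1, de_fc = 1.5,
                            dcl_rth = 0.5, dcl_qth = 0.1,
                            dcl_r_diffth = 0.5, dcl_q_diffth = 0.1,
                            lean_fdr = 0.1, star_alpha = 0.1,
                            subtype_fdr = 0.001,
                            lean_perm = 10000, consensus_reps = 1000,
                            k_max = 6, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(max_missing > 0, max_missing <= 1,
            de_fdr > 0, de_fdr < 1, de_fc >= 1,
            dcl_qth > 0, dcl_qth < 1, dcl_q_diffth > 0, dcl_q_diffth < 1,
            lean_fdr > 0, lean_fdr < 1, star_alpha > 0, star_alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write all synthetic inputs of a pipeline run to disk
#'
#' Generates a dataset with [generate_dataset()] (plus the external
#' mRNA mirror cohort) and writes every standard input the pipeline
#' reads: abundance TSV, design TSV, HIPPIE-style PPI edge list, a GMT
#' collection (the planted modules plus random decoy sets), survival
#' TSVs, the mirror expression TSV and the ground-truth JSON.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param n_decoy_sets Number of random decoy gene sets in the GMT.
#' @return A [pipeline_config()] pointing at the written files,
#'   invisibly.
#' @export
simulate_dataset <- function(config = synthetic_config(), dir,
                             n_decoy_sets = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config)
  mirror <- generate_mrna_mirror(ds$truth, config)
  pth <- function(f) file.path(dir, f)
  write_abundance(ds$abundance, pth("abundance.tsv"))
  write_design(ds$abundance$design, pth("design.tsv"))
  write_ppi(ds$network, pth("ppi.tsv"))

  proteins <- rownames(ds$abundance$values)
  sets <- list()
  ma <- ds$truth$module_assignments
  for (m in unique(ma)) {
    sets[[sprintf("planted_module_%d", m)]] <- sort(names(ma)[ma == m])
  }
  for (i in seq_len(n_decoy_sets)) {
    sets[[sprintf("decoy_set_%02d", i)]] <-
      sort(sample(proteins, sample(10:40, 1)))
  }
  write_gmt(sets, pth("genesets.gmt"))

  write_survival(survival_table(ds$survival$sample, ds$survival$time,
                                ds$survival$event, ds$survival$group),
                 pth("survival.tsv"))
  utils::write.table(
    data.frame(gene = rownames(mirror$expression), mirror$expression,
               check.names = FALSE),
    pth("mrna.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_survival(survival_table(mirror$survival$sample,
                                mirror$survival$time,
                                mirror$survival$event,
                                mirror$survival$group),
                 pth("mrna_survival.tsv"))
  write_truth(ds$truth, pth("truth.json"))
  invisible(pipeline_config(
    abundance = pth("abundance.tsv"), design = pth("design.tsv"),
    ppi = pth("ppi.tsv"), gmt = pth("genesets.gmt"),
    survival = pth("survival.tsv"), mrna = pth("mrna.tsv"),
    mrna_survival = pth("mrna_survival.tsv"), truth = pth("truth.json"),
    out_dir = file.path(dir, "out"), seed = config$seed))
}

#' Serialize / restore the planted ground truth
#' @param truth The `truth` element of [generate_dataset()].
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    de_proteins = truth$de_proteins,
    de_direction = as.list(truth$de_direction),
    module_assignments = as.list(truth$module_assignments),
    module_edges = truth$module_edges,
    subtype_labels = as.list(truth$subtype_labels),
    marker_proteins = truth$marker_proteins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(de_proteins = as.character(obj$de_proteins),
       de_direction = unlist(obj$de_direction),
       module_assignments = unlist(obj$module_assignments),
       module_edges = as.data.frame(obj$module_edges),
       subtype_labels = unlist(obj$subtype_labels),
       marker_proteins = as.character(obj$marker_proteins))
}

#' Run one pipeline stage or the full pipeline
#'
#' Stages (in order): `preprocess`, `de`, `dce`, `network`, `enrich`,
#' `subtype`, `survival`. Each stage reads its inputs (raw inputs from
#' the configured paths, intermediate results from `out_dir`), writes
#' its outputs as TSV into `out_dir`, and returns a named list of
#' record counts. `run_pipeline` executes all stages and writes a JSON
#' run manifest with the configuration hash and every count, which
#' fully determines reproduction.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @return The stage's count list (invisibly for `run_pipeline`, which
#'   returns the manifest).
#' @export
run_stage <- function(stage, config) {
  stages <- c("preprocess", "de", "dce", "network", "enrich", "subtype",
              "survival")
  stage <- match.arg(stage, stages)
  st <- pipeline_state(config)
  counts <- switch(stage,
    preprocess = stage_preprocess(st),
    de = stage_de(st),
    dce = stage_dce(st),
    network = stage_network(st),
    enrich = stage_enrich(st),
    subtype = stage_subtype(st),
    survival = stage_survival(st))
  message(sprintf("[%s] %s", stage,
                  paste(names(counts), unlist(counts), sep = "=",
                        collapse = " ")))
  counts
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  for (stage in c("preprocess", "de", "dce", "network", "enrich",
                  "subtype", "survival")) {
    counts <- c(counts, run_stage(stage, config))
  }
  manifest <- list(
    package = "dconet",
    version = as.character(utils::packageVersion("dconet")),
    seed = config$seed,
    config_hash = config_hash(config),
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# hash of the scientific configuration only: file locations are
# machine-specific and must not change the run identity
config_hash <- function(config) {
  paths <- c("abundance", "design", "ppi", "gmt", "survival", "mrna",
             "mrna_survival", "truth", "out_dir")
  cfg <- config[setdiff(sort(names(config)), paths)]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

# in-memory cache of one run's intermediates, backed by out_dir
pipeline_state <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$path <- function(f) file.path(config$out_dir, f)
  env
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("missing input for ", what, ": ",
         if (is.null(path)) "(not configured)" else path, call. = FALSE)
  }
  path
}

read_processed <- function(st) {
  p <- stage_output(st, "processed.tsv", "preprocess")
  read_abundance(p, read_design(st$path("processed_design.tsv")))
}

# path of an earlier stage's output, with a stage-order error when the
# producing stage has not run yet
stage_output <- function(st, file, producer) {
  p <- st$path(file)
  if (!file.exists(p)) {
    stop("stage-order violation: run the '", producer, "' stage first",
         call. = FALSE)
  }
  p
}

stage_preprocess <- function(st) {
  cfg <- st$config
  raw <- read_abundance(require_input(cfg$abundance, "preprocess"),
                        read_design(require_input(cfg$design, "preprocess")))
  pre <- preprocess(raw, max_missing = cfg$max_missing, k = cfg$knn_k)
  write_abundance(pre, st$path("processed.tsv"))
  write_design(pre$design, st$path("processed_design.tsv"))
  list(proteins_input = nrow(raw$values),
       proteins_retained = nrow(pre$values))
}

stage_de <- function(st) {
  cfg <- st$config
  pre <- read_processed(st)
  fit <- fit_moderated_t(pre)
  res <- call_de(fit$results, fdr_cut = cfg$de_fdr, fc_cut = cfg$de_fc)
  write_de_results(res, st$path("de.tsv"))
  list(de_up = sum(res$status == "up"), de_down = sum(res$status == "down"))
}

stage_dce <- function(st) {
  cfg <- st$config
  pre <- read_processed(st)
  links <- classify_dcl(all_pair_correlations(pre),
                        rth = cfg$dcl_rth, qth = cfg$dcl_qth,
                        r_diffth = cfg$dcl_r_diffth,
                        q_diffth = cfg$dcl_q_diffth)
  dcps <- find_dcps(links, qth = cfg$dcl_q_diffth)
  write_dcl_table(links, st$path("dcl.tsv"))
  utils::write.table(dcps, st$path("dcp.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  saveRDS(links, st$path("links.rds"))
  list(pairs_tested = nrow(links),
       coexpressed_links = sum(links$is_coexpressed),
       dcl = sum(links$is_dcl), dcp = sum(dcps$is_dcp))
}

read_links <- function(st) {
  readRDS(stage_output(st, "links.rds", "dce"))
}

stage_network <- function(st) {
  cfg <- st$config
  net <- load_ppi(require_input(cfg$ppi, "network"))
  de <- utils::read.delim(stage_output(st, "de.tsv", "de"))
  links <- read_links(st)
  de_p <- structure(de$p, names = de$protein)
  stars <- lean_scan(net, de_p, n_perm = cfg$lean_perm, seed = cfg$seed)
  kept <- filter_stars_by_dc(stars, net, links, alpha = cfg$star_alpha,
                             lean_fdr_cut = cfg$lean_fdr)
  unified <- build_unified_network(kept[kept$kept, , drop = FALSE],
                                   net, links)
  dcps <- utils::read.delim(stage_output(st, "dcp.tsv", "dce"))
  unified <- annotate_nodes(unified, de_results = de, dcps = dcps)
  write_network(unified, st$path("unified.tsv"))
  utils::write.table(as.data.frame(kept)[, setdiff(colnames(kept), "kept")],
                     st$path("stars.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(stars_significant = nrow(kept), stars_retained = sum(kept$kept),
       unified_nodes = igraph::vcount(unified),
       unified_edges = igraph::ecount(unified))
}

stage_enrich <- function(st) {
  cfg <- st$config
  if (is.null(cfg$gmt)) return(list(enriched_sets = 0L))
  sets <- read_gmt(require_input(cfg$gmt, "enrich"))
  pre <- read_processed(st)
  universe <- rownames(pre$values)
  de <- utils::read.delim(stage_output(st, "de.tsv", "de"))
  links <- read_links(st)
  query <- de$protein[de$status != "ns"]
  n_sig <- 0L
  if (length(query)) {
    res <- ora(query, sets, universe)
    utils::write.table(res, st$path("enrich_de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n_sig <- sum(res$significant)
  }
  lp <- link_pathway_enrichment(links, sets)
  if (!is.null(lp)) {
    utils::write.table(lp, st$path("enrich_links.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(enriched_sets = n_sig,
       link_enriched_sets = if (is.null(lp)) 0L else sum(lp$fdr < 0.1))
}

stage_subtype <- function(st) {
  cfg <- st$config
  pre <- read_processed(st)
  cc <- consensus_cluster(pre, k_max = cfg$k_max,
                          reps = cfg$consensus_reps, seed = cfg$seed,
                          chosen_k = 2)
  labels <- cc$labels[[as.character(cc$chosen_k)]]
  utils::write.table(data.frame(sample = names(labels), subtype = labels),
                     st$path("subtypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cc$consensus[[as.character(cc$chosen_k)]],
                     st$path("consensus_k2.tsv"), sep = "\t",
                     quote = FALSE)
  if (min(table(labels)) < 2) {
    warning("a subtype has fewer than 2 samples; marker stage skipped")
    return(list(chosen_k = cc$chosen_k, subtype_markers = 0L))
  }
  mk <- subtype_markers(pre, labels, fdr_cut = cfg$subtype_fdr)
  write_de_results(mk[, setdiff(colnames(mk), "status")],
                   st$path("subtype_markers.tsv"))
  list(chosen_k = cc$chosen_k, subtype_markers = sum(mk$is_marker))
}

stage_survival <- function(st) {
  cfg <- st$config
  if (is.null(cfg$survival)) return(list(logrank_p = NA_real_))
  surv <- read_survival(require_input(cfg$survival, "survival"))
  lr <- logrank_test(surv)
  counts <- list(logrank_chi2 = lr$chi2, logrank_p = lr$p)
  if (!is.null(cfg$mrna) && file.exists(cfg$mrna)) {
    mk <- utils::read.delim(stage_output(st, "subtype_markers.tsv",
                                         "subtype"))
    markers <- mk$protein[mk$is_marker]
    mrna <- utils::read.delim(cfg$mrna, check.names = FALSE)
    expr <- as.matrix(mrna[, -1]); rownames(expr) <- mrna[[1]]
    if (sum(markers %in% rownames(expr)) >= 10) {
      val <- validate_signature(expr, markers, k = 2,
                                reps = cfg$consensus_reps,
                                seed = cfg$seed)
      ext <- read_survival(cfg$mrna_survival)
      ext$group <- paste0("cluster", val$labels[ext$sample])
      lr2 <- logrank_test(ext)
      utils::write.table(
        data.frame(sample = names(val$labels), cluster = val$labels),
        st$path("mrna_clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      counts$mrna_logrank_p <- lr2$p
    }
  }
  counts
}
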