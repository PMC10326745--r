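#' Configuration of the synthetic proteomics study
#'
#' Collects every knob of the synthetic-data generator. The defaults
#' emulate the study design the pipeline targets: 30 tumor and 22
#' control samples, 2000 quantified proteins on the log2 intensity
#' scale, a planted 10-protein co-expression module that is tightly
#' correlated in tumors (`r_case = 0.9`) and uncorrelated in controls,
#' roughly 8% differentially expressed proteins shifted by 1.5 log2
#' units, intensity-dependent missingness, two tumor subtypes in a
#' 60/40 split separated by 1.5 log2 units on 100 marker proteins, and
#' subtype-linked survival with hazard ratio 3.
#'
#' @param n_case,n_ctrl Tumor and control sample counts.
#' @param n_proteins Number of proteins.
#' @param de_fraction Fraction of proteins with shifted means in cases.
#' @param de_log2fc Magnitude of the planted mean shift (log2 units).
#' @param de_in_modules Plant differential expression on every module
#'   member (the dysregulated-module scenario the network stage is
#'   designed to recover).
#' @param n_modules,module_size Number and size of planted
#'   co-expression modules.
#' @param r_case,r_ctrl Target within-module pairwise correlation in
#'   each group (|r| < 1).
#' @param missing_fraction Marginal missingness rate.
#' @param mnar_weight Fraction of the missingness concentrated in
#'   low-abundance entries (logistic intensity-dependent dropout).
#' @param n_subtypes Subtypes inside the case group (1 disables the
#'   subtype structure).
#' @param n_markers Number of subtype-marker proteins.
#' @param subtype_effect Log2 shift of marker proteins between the case
#'   subtypes.
#' @param survival_hazard_ratio Hazard ratio of subtype 2 over
#'   subtype 1.
#' @param seed Random seed; a fixed seed makes every output
#'   reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 30, n_ctrl = 22, n_proteins = 2000,
                             de_fraction = 0.08, de_log2fc = 1.5,
                             de_in_modules = TRUE,
                             n_modules = 1, module_size = 10,
                             r_case = 0.9, r_ctrl = 0,
                             missing_fraction = 0.10, mnar_weight = 0.5,
                             n_subtypes = 2, n_markers = 100,
                             subtype_effect = 1.5,
                             survival_hazard_ratio = 3, seed = 1) {
  cfg <- list(n_case = n_case, n_ctrl = n_ctrl, n_proteins = n_proteins,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              de_in_modules = de_in_modules,
              n_modules = n_modules, module_size = module_size,
              r_case = r_case, r_ctrl = r_ctrl,
              missing_fraction = missing_fraction,
              mnar_weight = mnar_weight,
              n_subtypes = n_subtypes, n_markers = n_markers,
              subtype_effect = subtype_effect,
              survival_hazard_ratio = survival_hazard_ratio, seed = seed)
  stopifnot(n_case > 0, n_ctrl > 0, n_proteins > 0, n_modules >= 0,
            de_fraction >= 0, de_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            mnar_weight >= 0, mnar_weight <= 1,
            abs(r_case) < 1, abs(r_ctrl) < 1, n_subtypes >= 1)
  if (n_modules * module_size > n_proteins) {
    stop("module_size * n_modules exceeds n_proteins")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic proteomics study with known ground truth
#'
#' Draws baseline log2 abundances per protein from a normal with
#' protein-specific mean and variance (the variances follow a scaled
#' inverse chi-square, so that variance moderation has something to
#' shrink). Planted differentially expressed proteins are shifted by
#' `+-de_log2fc` in the cases. Each planted module is generated from a
#' shared latent factor, `x = sqrt(rho) f + sqrt(1-rho) e`, giving an
#' expected pairwise correlation of exactly `rho` per group. Module
#' members are wired as cliques into an interaction network whose
#' background edges come from preferential attachment (heavy-tailed
#' degrees, as in curated PPI resources). Missingness is a mixture of
#' uniform dropout and logistic intensity-dependent dropout. Case
#' samples carry a two-subtype structure on marker proteins and
#' subtype-linked exponential survival with uniform censoring.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `abundance` (an [abundance_table()] with
#'   missing entries), `network` (an undirected [igraph][igraph::graph]
#'   PPI), `truth` (planted structure: `de_proteins`, `de_direction`,
#'   `module_assignments`, `module_edges`, `subtype_labels`,
#'   `marker_proteins`) and `survival` (per case sample: `time`,
#'   `event`, `group`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(p))
  cases <- sprintf("T%02d", seq_len(config$n_case))
  ctrls <- sprintf("N%02d", seq_len(config$n_ctrl))
  design <- structure(c(rep("case", config$n_case),
                        rep("control", config$n_ctrl)),
                      names = c(cases, ctrls))

  mu <- stats::rnorm(p, mean = 25, sd = 3)
  sdv <- sqrt(0.25 * 6 / stats::rchisq(p, df = 6))
  n <- config$n_case + config$n_ctrl

  values <- mu + sdv * matrix(stats::rnorm(p * n), p, n)
  dimnames(values) <- list(proteins, c(cases, ctrls))

  # planted co-expression modules via a shared latent factor per group
  module_assignments <- integer(0)
  module_edges <- NULL
  module_members <- character(0)
  if (config$n_modules > 0 && config$module_size > 1) {
    pool <- sample(proteins, config$n_modules * config$module_size)
    module_assignments <- structure(
      rep(seq_len(config$n_modules), each = config$module_size),
      names = pool)
    module_members <- pool
    for (m in seq_len(config$n_modules)) {
      mem <- pool[module_assignments[pool] == m]
      values[mem, cases] <- mu[match(mem, proteins)] +
        sdv[match(mem, proteins)] *
        latent_factor_block(length(mem), config$n_case, config$r_case)
      values[mem, ctrls] <- mu[match(mem, proteins)] +
        sdv[match(mem, proteins)] *
        latent_factor_block(length(mem), config$n_ctrl, config$r_ctrl)
      pairs <- t(utils::combn(sort(mem), 2))
      module_edges <- rbind(module_edges,
                            data.frame(protein_a = pairs[, 1],
                                       protein_b = pairs[, 2],
                                       module = m,
                                       stringsAsFactors = FALSE))
    }
  }

  # planted differential expression
  n_de <- round(config$de_fraction * p)
  de_proteins <- character(0)
  if (config$de_in_modules) de_proteins <- module_members
  extra <- setdiff(proteins, de_proteins)
  if (n_de > length(de_proteins)) {
    de_proteins <- c(de_proteins,
                     sample(extra, n_de - length(de_proteins)))
  }
  de_direction <- structure(sample(c(1, -1), length(de_proteins),
                                   replace = TRUE),
                            names = de_proteins)
  if (length(de_proteins)) {
    values[de_proteins, cases] <- values[de_proteins, cases] +
      de_direction * config$de_log2fc
  }

  # subtype structure on marker proteins (case samples only)
  subtype_labels <- structure(rep(1L, config$n_case), names = cases)
  marker_proteins <- character(0)
  if (config$n_subtypes > 1) {
    n1 <- round(0.6 * config$n_case)
    subtype_labels[] <- c(rep(1L, n1), rep(2L, config$n_case - n1))
    marker_proteins <- sample(setdiff(proteins, module_members),
                              config$n_markers)
    s2_samples <- cases[subtype_labels == 2L]
    shift <- sample(c(1, -1), config$n_markers, replace = TRUE) *
      config$subtype_effect
    values[marker_proteins, s2_samples] <-
      values[marker_proteins, s2_samples] + shift
  }

  # interaction network: preferential-attachment background + module cliques
  g <- igraph::sample_pa(p, m = 2, directed = FALSE)
  igraph::V(g)$name <- sample(proteins)
  if (!is.null(module_edges)) {
    g <- igraph::add_edges(g, t(as.matrix(module_edges[, 1:2])))
  }
  g <- igraph::simplify(g)

  # missingness: mixture of uniform and intensity-dependent dropout
  if (config$missing_fraction > 0) {
    w <- stats::plogis((stats::quantile(values, 0.2) - values) /
                         (stats::sd(values) / 2))
    prob <- config$missing_fraction *
      ((1 - config$mnar_weight) + config$mnar_weight * w / mean(w))
    prob <- pmin(prob, 0.95)
    values[matrix(stats::runif(p * n), p, n) < prob] <- NA
  }

  survival <- simulate_survival(subtype_labels,
                                config$survival_hazard_ratio)

  truth <- list(de_proteins = de_proteins, de_direction = de_direction,
                module_assignments = module_assignments,
                module_edges = module_edges,
                subtype_labels = subtype_labels,
                marker_proteins = marker_proteins)
  list(abundance = abundance_table(values, design), network = g,
       truth = truth, survival = survival)
}

# module members as sqrt(rho) * shared factor + sqrt(1-rho) * noise:
# expected pairwise correlation exactly rho, unit marginal variance.
# A common negative pairwise correlation of a whole module is not
# geometrically realisable, so rho must be non-negative.
latent_factor_block <- function(n_members, n_samples, rho) {
  if (rho < 0) stop("within-module target correlation must be >= 0")
  # the factor realisation is standardised so the planted correlation is
  # controlled rather than drawn (its realised variance would otherwise
  # fluctuate strongly at n ~ 30)
  f <- matrix(as.numeric(scale(stats::rnorm(n_samples))),
              n_members, n_samples, byrow = TRUE)
  e <- matrix(stats::rnorm(n_members * n_samples), n_members, n_samples)
  sqrt(rho) * f + sqrt(1 - rho) * e
}

# exponential survival times with a subtype hazard ratio and uniform
# censoring; time unit: months, baseline median 60
simulate_survival <- function(subtype_labels, hazard_ratio) {
  base <- log(2) / 60
  lambda <- base * ifelse(subtype_labels == 2L, hazard_ratio, 1)
  t_ev <- stats::rexp(length(lambda), rate = lambda)
  t_cn <- stats::runif(length(lambda), 12, 120)
  data.frame(sample = names(subtype_labels),
             time = pmin(t_ev, t_cn),
             event = as.integer(t_ev <= t_cn),
             group = paste0("subtype", subtype_labels),
             stringsAsFactors = FALSE)
}

#' Generate an independent mRNA mirror cohort
#'
#' Produces an external expression cohort over the same gene universe in
#' which the subtype-marker genes carry the planted subtype structure
#' plus Gaussian noise, together with subtype-linked survival. Used to
#' test cross-dataset validation of a subtype signature.
#'
#' @param truth The `truth` element of [generate_dataset()].
#' @param config The [synthetic_config()] used for the discovery set.
#' @param n_samples Size of the external cohort (default 113).
#' @param noise_sd Per-gene Gaussian noise, log2 units.
#' @param seed Random seed (defaults to `config$seed + 1`).
#' @return A list with `expression` (genes x samples matrix),
#'   `subtype_labels` (named integer vector) and `survival`.
#' @export
generate_mrna_mirror <- function(truth, config, n_samples = 113,
                                 noise_sd = 1, seed = config$seed + 1) {
  if (n_samples < 2 * config$n_subtypes) {
    stop("n_samples must be at least twice the number of subtypes")
  }
  set.seed(seed)
  genes <- sprintf("P%04d", seq_len(config$n_proteins))
  samples <- sprintf("E%03d", seq_len(n_samples))
  n1 <- round(0.6 * n_samples)
  subtype <- structure(c(rep(1L, n1), rep(2L, n_samples - n1)),
                       names = samples)
  # per-gene baseline expression plus per-entry noise
  mu <- stats::rnorm(length(genes), sd = 2)
  expr <- mu + matrix(stats::rnorm(length(genes) * n_samples,
                                   sd = noise_sd),
                      length(genes), n_samples,
                      dimnames = list(genes, samples))
  mk <- truth$marker_proteins
  if (length(mk)) {
    shift <- sample(c(1, -1), length(mk), replace = TRUE) *
      config$subtype_effect
    expr[mk, subtype == 2L] <- expr[mk, subtype == 2L] + shift
  }
  survival <- simulate_survival(subtype, config$survival_hazard_ratio)
  list(expression = expr, subtype_labels = subtype, survival = survival)
}
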