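# dconet

Integrative differential expression and differential co-expression
network analysis for two-group label-free proteomics.

Tumor/control proteome studies usually stop at per-protein differential
expression. `dconet` implements the complementary, network-level view
for researchers analysing log2 protein abundance matrices (e.g. iBAQ):
which protein *pairs* change their co-regulation between conditions,
which interaction neighbourhoods concentrate the dysregulation, and
whether the tumor group hides molecular subtypes with different
survival.

## The analysis

Starting from a proteins × samples matrix of log2 abundances with a
two-group design, an undirected protein–protein interaction (PPI)
network, gene-set collections (GMT) and an optional survival table:

1. **Preprocessing** — quantile normalization, removal of proteins with
   ≥ 40% missing values, k-nearest-neighbour imputation (k = 10).
2. **Differential expression** — per-protein two-group linear model
   with empirical-Bayes variance moderation. With residual variances
   `s²_g` on `d_g` df and a scaled-F prior `s²_g ~ s₀² F(d_g, d₀)`
   fitted by digamma/trigamma moment matching, the moderated statistic
   is `t̃_g = β_g / (s̃_g √(1/n₁ + 1/n₂))`,
   `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, on `d₀ + d_g` df. Calls:
   FDR < 0.1 and fold change > 1.5.
3. **Differential co-expression** — per-group Pearson correlations for
   every protein pair, compared by the Fisher Z difference test
   `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`. A pair is a
   differentially co-expressed link (DCL) when it is strongly
   co-expressed in at least one group (|r| > 0.5, FDR < 0.1) and the
   difference is large and significant (|Δr| > 0.5, FDR < 0.1 among the
   co-expressed links). Proteins carrying more DCLs than a global-rate
   binomial model expects (FDR < 0.1) are differentially co-expressed
   proteins (DCPs). Link-level pathway enrichment uses Fisher's exact
   test over pairs whose both members sit in a gene set.
4. **Network integration** — every protein's star (itself plus direct
   PPI neighbours) is scored for enrichment of small DE p-values by the
   minimum binomial order-statistic tail, calibrated against random
   member sets; significant stars (FDR < 0.1) are further filtered for
   DCL enrichment (Fisher's exact test, Holm-adjusted p < 0.1), pruned
   to their DCL edges, reduced to their maximum connected component and
   merged into the unified dysregulated network, whose every edge is
   both a PPI interaction and a DCL.
5. **Subtypes and survival** — consensus clustering (1000 subsamples of
   80%, hierarchical clustering on 1 − Pearson correlation, k up to 6)
   of the tumor samples; subtype markers at FDR < 0.001; validation by
   re-clustering an external cohort restricted to the markers; group
   comparison by Kaplan–Meier curves and the log-rank test.

A synthetic-data generator (`generate_dataset()`) produces the whole
input bundle with planted ground truth — shifted proteins, a latent
factor co-expression module wired into a preferential-attachment PPI
network, intensity-dependent missingness, two tumor subtypes and
subtype-linked survival — so every stage is testable end to end.

## Worked example

```r
library(dconet)

dir <- tempfile()
cfg <- simulate_dataset(synthetic_config(n_proteins = 250, seed = 11), dir)
cfg$lean_perm <- 500
cfg$consensus_reps <- 100
manifest <- run_pipeline(cfg)
```

The stage log prints the record counts after every filter:

```
[preprocess] proteins_input=250 proteins_retained=250
[de] de_up=32 de_down=33
[dce] pairs_tested=31125 coexpressed_links=3685 dcl=2648 dcp=82
[network] stars_significant=10 stars_retained=10 unified_nodes=10 unified_edges=28
[enrich] enriched_sets=2 link_enriched_sets=5
[subtype] chosen_k=2 subtype_markers=88
[survival] logrank_chi2=9.47756486734461 logrank_p=0.0020799987608127 mrna_logrank_p=3.18504742982752e-07
```

Reading the funnel: of 31,125 tested pairs, 3,685 are co-expressed in
at least one group and 2,648 change significantly between groups; the
local scan finds 10 DE-enriched stars, all of which survive the
DCL-enrichment filter, merging into a 10-node / 28-edge unified network
that contains the planted dysregulated module. Consensus clustering
fixes k = 2 and finds 88 subtype markers; the planted subtypes separate
survival both in the discovery cohort (log-rank p = 0.002) and, via the
marker signature, in the external mRNA mirror cohort (p = 3.2e-07).
`out/manifest.json` records the configuration hash and every count; the
same seed reproduces it byte for byte.

The same stages are exposed individually (`preprocess()`,
`fit_moderated_t()`, `all_pair_correlations()`, `classify_dcl()`,
`find_dcps()`, `lean_scan()`, `build_unified_network()`, `ora()`,
`consensus_cluster()`, `validate_signature()`, `km_curve()`,
`logrank_test()`), and a thin command-line wrapper lives in
`inst/scripts/dconet-cli.R`.

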