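{
  "package": "dconet",
  "version": "0.1.0",
  "seed": 11,
  "config_hash": "3fbdb8c2f9fd9165ea88e75e8f68a12c",
  "counts": {
    "proteins_input": 250,
    "proteins_retained": 250,
    "de_up": 32,
    "de_down": 33,
    "pairs_tested": 31125,
    "coexpressed_links": 3685,
    "dcl": 2648,
    "dcp": 82,
    "stars_significant": 10,
    "stars_retained": 10,
    "unified_nodes": 10,
    "unified_edges": 28,
    "enriched_sets": 2,
    "link_enriched_sets": 5,
    "chosen_k": 2,
    "subtype_markers": 88,
    "logrank_chi2": 9.47756486734461,
    "logrank_p": 0.0020799987608127,
    "mrna_logrank_p": 3.18504742982752e-07
  }
}
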