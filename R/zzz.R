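# quiet R CMD check notes for data.table non-standard evaluation symbols
utils::globalVariables(c(
  ".", ".N", "keep", "fdr", "odds_ratio", "cooc_frac", "marginal_a",
  "marginal_b", "gene_a", "gene_b", "cancer_code", "erg_class", "category",
  "chromosome", "any_cna_frac", "pass", "p_value", "method", "direction",
  "comparison", "guide_id", "gene", "consensus", "pattern", "candidate"
))
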