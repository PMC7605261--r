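#' Analysis thresholds and weights
#'
#' Single container for every numeric constant used across the pipeline, so
#' that no cutoff is hard-coded at a call site. Defaults follow the study
#' design this package implements: genes count as altered in a cancer type
#' when at least 1% of samples carry the aberration; the copy-number track of
#' the mutation-vs-CNA classification requires 10%; driver-track
#' qualification requires 5% of samples in at least one cancer type;
#' expression aberration means |Z| > 2, with the Pan-Cancer Driver Z track
#' requiring 15% of samples beyond that cut; differential expression keeps
#' genes with >= 10 total reads, |log10 FC| above `logfc_cut` and FDR < 0.05;
#' CNA- and SNA-expression correlations are filtered at R-squared > 30% and
#' 10% respectively with FDR < 0.05; co-occurrence meta-analysis keeps
#' cancers where both genes are altered together in at least `cooc_min_frac`
#' of samples; the four driver tracks are combined with weights 1 (SNA),
#' 1 (CNA), 0.5 (Z) and 0.5 (FC); the screen consensus uses per-method
#' p-value cuts of 0.001 and 0.01.
#'
#' @param altered_min_frac minimum altered-sample fraction for a gene to
#'   count as altered in a cancer type (default 0.01).
#' @param cna_track_min_frac CNA fraction above which a gene is classed as
#'   amplified/deleted rather than only mutated (default 0.10).
#' @param driver_freq_min_frac per-cancer sample fraction a track needs for
#'   that cancer to count toward the primary driver rank (default 0.05).
#' @param z_cut absolute expression Z-score defining an aberrant sample.
#' @param z_sample_frac fraction of samples with |Z| > `z_cut` needed for the
#'   Z driver track (default 0.15).
#' @param logfc_cut absolute log10 fold-change cut for the DE filter and the
#'   FC driver track (default 1; 2 is the stricter alternative).
#' @param de_fdr FDR cut for differential expression.
#' @param de_min_reads minimum total read coverage for a gene to be tested.
#' @param r2_cna,r2_sna R-squared filters for CNA- and SNA-expression
#'   correlation records.
#' @param fdr_sig generic FDR significance level.
#' @param cooc_min_frac both-altered sample fraction required of significant
#'   co-occurrent pairs (0.05 or 0.10 depending on the analysis).
#' @param weights named numeric vector of track weights (sna, cna, z, fc).
#' @param twice_rule_ratio prevalence ratio above which one CNA direction
#'   wins over the other in gene-level categories (default 2).
#' @param screen_p named numeric vector of per-method p-value thresholds for
#'   screen consensus calls.
#'
#' @return A list of class `erg_thresholds`.
#' @export
#' @examples
#' th <- analysis_thresholds()
#' th$driver_freq_min_frac
analysis_thresholds <- function(altered_min_frac = 0.01,
                                cna_track_min_frac = 0.10,
                                driver_freq_min_frac = 0.05,
                                z_cut = 2.0,
                                z_sample_frac = 0.15,
                                logfc_cut = 1.0,
                                de_fdr = 0.05,
                                de_min_reads = 10,
                                r2_cna = 0.30,
                                r2_sna = 0.10,
                                fdr_sig = 0.05,
                                cooc_min_frac = 0.05,
                                weights = c(sna = 1, cna = 1, z = 0.5, fc = 0.5),
                                twice_rule_ratio = 2.0,
                                screen_p = c(methodA = 0.001, methodB = 0.01)) {
  fracs <- c(altered_min_frac, cna_track_min_frac, driver_freq_min_frac,
             z_sample_frac, de_fdr, r2_cna, r2_sna, fdr_sig, cooc_min_frac)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1))
    stop("all fraction thresholds must lie in [0, 1]", call. = FALSE)
  if (any(weights <= 0)) stop("track weights must be positive", call. = FALSE)
  stopifnot(all(c("sna", "cna", "z", "fc") %in% names(weights)))
  structure(list(
    altered_min_frac = altered_min_frac,
    cna_track_min_frac = cna_track_min_frac,
    driver_freq_min_frac = driver_freq_min_frac,
    z_cut = z_cut,
    z_sample_frac = z_sample_frac,
    logfc_cut = logfc_cut,
    de_fdr = de_fdr,
    de_min_reads = de_min_reads,
    r2_cna = r2_cna,
    r2_sna = r2_sna,
    fdr_sig = fdr_sig,
    cooc_min_frac = cooc_min_frac,
    weights = weights,
    twice_rule_ratio = twice_rule_ratio,
    screen_p = screen_p
  ), class = "erg_thresholds")
}

#' The twelve ERG functional classes
#'
#' Histone methylation/acetylation and DNA methylation regulators split into
#' writers (w), editors (e) and readers (r), plus chromatin remodeling
#' complex members (ChRC), helicases, and other chromatin modifiers.
#'
#' @return Character vector of the 12 class labels.
#' @export
erg_classes <- function() {
  c("HM_e", "HM_w", "HM_r", "DM_w", "DM_e", "DM_r",
    "HA_e", "HA_w", "HA_r", "ChRC", "helicase", "other")
}

#' The ten hallmarks of cancer used for enrichment
#' @return Character vector of 10 hallmark labels.
#' @export
hallmark_labels <- function() {
  c("sustaining_proliferative_signaling", "evading_growth_suppressors",
    "resisting_cell_death", "enabling_replicative_immortality",
    "inducing_angiogenesis", "activating_invasion_metastasis",
    "genome_instability_mutation", "tumor_promoting_inflammation",
    "deregulating_cellular_energetics", "avoiding_immune_destruction")
}
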