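# Alteration landscape: per-gene per-cancer frequencies, the six-way
# sample/gene category rules, and class/chromosome stratified summaries.
# Deep events (calls +/-2) drive category labels; shallow calls (+/-1) only
# contribute to the all-CNA burden columns.

.sample_category_levels <- c("none", "SNA", "amp", "amp_SNA", "del", "del_SNA")

#' Classify a (gene, sample) observation into an alteration category
#'
#' Deep amplification with a mutation gives `amp_SNA`, deep deletion with a
#' mutation `del_SNA`, deep events alone `amp`/`del`, mutation alone `SNA`,
#' anything else (including shallow-only CNAs) `none`. The six labels are
#' mutually exclusive and exhaustive over the (mutation presence x CNA call)
#' grid.
#'
#' @param sna_count nonnegative mutation count(s).
#' @param cna_call CNA call(s) in \{-2,-1,0,1,2\}; vectorized.
#' @return Character vector of category labels.
#' @export
classify_sample_category <- function(sna_count, cna_call) {
  stopifnot(all(cna_call %in% -2:2))
  has_sna <- sna_count > 0
  out <- rep("none", length(has_sna))
  out[cna_call == 2 & has_sna] <- "amp_SNA"
  out[cna_call == 2 & !has_sna] <- "amp"
  out[cna_call == -2 & has_sna] <- "del_SNA"
  out[cna_call == -2 & !has_sna] <- "del"
  out[abs(cna_call) != 2 & has_sna] <- "SNA"
  out
}

#' Per-gene alteration frequencies for one cohort
#'
#' Computes, per gene, the fraction of samples with at least one
#' nonsynonymous mutation, the deep (+/-2) and shallow (+/-1) CNA fractions
#' per direction, and the any-CNA burden (all four nonzero codes), together
#' with sample-level category counts used by the gene-level classifier.
#' Genes requested but absent from the matrices are reported with `NA`
#' frequencies rather than zero.
#'
#' @param cohort a [cohort_omics()] object.
#' @param genes genes to report (default: the cohort's gene axis).
#' @return data.frame, one row per gene, with columns gene, cancer_code,
#'   n_samples, sna_frac, deep_amp_frac, deep_del_frac, shallow_amp_frac,
#'   shallow_del_frac, any_cna_frac and n_cat_* sample-category counts.
#' @export
compute_alteration_frequencies <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "cohort_omics"))
  if (is.null(genes)) genes <- cohort$genes
  n <- length(cohort$samples)
  present <- genes %in% cohort$genes
  res <- data.frame(gene = genes, cancer_code = cohort$cancer_code,
                    n_samples = n,
                    sna_frac = NA_real_, deep_amp_frac = NA_real_,
                    deep_del_frac = NA_real_, shallow_amp_frac = NA_real_,
                    shallow_del_frac = NA_real_, any_cna_frac = NA_real_,
                    stringsAsFactors = FALSE)
  for (lv in .sample_category_levels)
    res[[paste0("n_cat_", lv)]] <- NA_integer_
  if (any(present)) {
    g <- genes[present]
    sna <- cohort$sna[g, , drop = FALSE]
    cna <- cohort$cna[g, , drop = FALSE]
    res$sna_frac[present] <- rowMeans(sna > 0)
    res$deep_amp_frac[present] <- rowMeans(cna == 2)
    res$deep_del_frac[present] <- rowMeans(cna == -2)
    res$shallow_amp_frac[present] <- rowMeans(cna == 1)
    res$shallow_del_frac[present] <- rowMeans(cna == -1)
    res$any_cna_frac[present] <- rowMeans(cna != 0)
    cats <- matrix(classify_sample_category(as.vector(sna), as.vector(cna)),
                   nrow = length(g))
    for (lv in .sample_category_levels)
      res[[paste0("n_cat_", lv)]][present] <- as.integer(rowSums(cats == lv))
  }
  res
}

#' Gene-level alteration category
#'
#' Applies the altered-gene rules: a gene is `none` unless at least one of
#' its mutation, deep-amplification or deep-deletion fractions reaches
#' `altered_min_frac` (1%). When both deep CNA directions qualify, the
#' direction at least `twice_rule_ratio` times as prevalent as the other
#' wins; otherwise the gene is `ma` (multiple alterations). When a mutation
#' signal and one CNA direction both qualify, the label (pure SNA, pure CNA,
#' or the co-occurring `amp_SNA`/`del_SNA` subtype) is decided by plurality
#' over the sample-level categories, ties giving `ma`.
#'
#' @param profile output of [compute_alteration_frequencies()] (one or more
#'   rows).
#' @param thresholds an [analysis_thresholds()] object.
#' @return Character vector of categories, one per profile row.
#' @export
classify_gene_category <- function(profile, thresholds = analysis_thresholds()) {
  t1 <- thresholds$altered_min_frac
  ratio <- thresholds$twice_rule_ratio
  vapply(seq_len(nrow(profile)), function(i) {
    p <- profile[i, ]
    if (is.na(p$sna_frac)) return(NA_character_)
    q_sna <- p$sna_frac >= t1
    q_amp <- p$deep_amp_frac >= t1
    q_del <- p$deep_del_frac >= t1
    if (!q_sna && !q_amp && !q_del) return("none")
    cna_dir <- NULL
    if (q_amp && q_del) {
      if (p$deep_amp_frac >= ratio * p$deep_del_frac) cna_dir <- "amp"
      else if (p$deep_del_frac >= ratio * p$deep_amp_frac) cna_dir <- "del"
      else return("ma")
    } else if (q_amp) cna_dir <- "amp" else if (q_del) cna_dir <- "del"
    if (!q_sna) return(cna_dir)
    if (is.null(cna_dir)) return("SNA")
    co_lab <- paste0(cna_dir, "_SNA")
    votes <- c(SNA = p$n_cat_SNA,
               pure = p[[paste0("n_cat_", cna_dir)]],
               co = p[[paste0("n_cat_", co_lab)]])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) return("ma")
    switch(top, SNA = "SNA", pure = cna_dir, co = co_lab)
  }, character(1))
}

#' Class- and chromosome-stratified landscape summaries
#'
#' Per (cancer, functional class): the fraction of class members with a
#' category other than `none`, plus the per-category split. Per (cancer,
#' chromosome): the mean any-CNA burden over resident genes, in a
#' circos-ready layout.
#'
#' @param profiles [compute_alteration_frequencies()] rows (possibly several
#'   cancers) carrying a `category` column (add one with
#'   [classify_gene_category()]).
#' @param annotation compendium annotation data.frame covering every gene.
#' @return List with data.frames `by_class` and `by_chromosome`.
#' @export
stratify_summaries <- function(profiles, annotation) {
  if (!"category" %in% names(profiles))
    stop("profiles must carry a 'category' column", call. = FALSE)
  missing_ann <- setdiff(unique(profiles$gene), annotation$symbol)
  if (length(missing_ann) > 0L)
    stop(sprintf("unannotated genes: %s", paste(missing_ann, collapse = ", ")),
         call. = FALSE)
  idx <- match(profiles$gene, annotation$symbol)
  profiles$erg_class <- annotation$erg_class[idx]
  profiles$chromosome <- annotation$chromosome[idx]
  dt <- as.data.table(profiles)

  cats <- c("SNA", "amp", "amp_SNA", "del", "del_SNA", "ma")
  by_class <- dt[, {
    out <- list(n_genes = .N,
                frac_altered = mean(category != "none", na.rm = TRUE))
    for (cc in cats)
      out[[paste0("frac_", cc)]] <- mean(category == cc, na.rm = TRUE)
    out
  }, by = .(cancer_code, erg_class)]
  absent <- setdiff(erg_classes(), unique(dt$erg_class))
  if (length(absent) > 0L)
    warning(sprintf("functional classes with no genes in input omitted: %s",
                    paste(absent, collapse = ", ")))
  by_chrom <- dt[!is.na(chromosome),
                 .(n_genes = .N,
                   mean_any_cna_frac = mean(any_cna_frac, na.rm = TRUE)),
                 by = .(cancer_code, chromosome)]
  setorderv(by_class, c("cancer_code", "erg_class"))
  setorderv(by_chrom, c("cancer_code", "chromosome"))
  list(by_class = as.data.frame(by_class),
       by_chromosome = as.data.frame(by_chrom))
}

#' Full landscape for a list of cohorts
#'
#' Convenience wrapper: frequencies plus gene-level categories for every
#' cohort, row-bound.
#'
#' @param cohorts named list of [cohort_omics()] objects.
#' @param thresholds an [analysis_thresholds()] object.
#' @return data.frame of profiles with a `category` column.
#' @export
alteration_landscape <- function(cohorts, thresholds = analysis_thresholds()) {
  out <- lapply(cohorts, function(co) {
    pr <- compute_alteration_frequencies(co)
    pr$category <- classify_gene_category(pr, thresholds)
    pr
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
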