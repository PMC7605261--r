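# Expression integration: Z-score aberration rates, alteration-expression
# correlation with the R^2/FDR filters, and promoter eQTM scanning.

#' Per-gene expression Z-score aberration rates
#'
#' Fraction of non-missing samples with Z above `z_cut` (up) and below
#' `-z_cut` (down); missing cells are excluded from the denominator, and
#' genes with all-missing Z get `NA` for both fractions.
#'
#' @param expr_z gene x sample Z-score matrix (NA allowed).
#' @param z_cut absolute Z defining an aberrant sample (default 2).
#' @return data.frame(gene, n_obs, up_frac, down_frac).
#' @export
zscore_aberration_rates <- function(expr_z, z_cut = 2) {
  n_obs <- rowSums(!is.na(expr_z))
  up <- rowSums(expr_z > z_cut, na.rm = TRUE)
  down <- rowSums(expr_z < -z_cut, na.rm = TRUE)
  data.frame(gene = rownames(expr_z), n_obs = n_obs,
             up_frac = ifelse(n_obs > 0, up / n_obs, NA_real_),
             down_frac = ifelse(n_obs > 0, down / n_obs, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate genetic alteration with expression Z-scores
#'
#' Per gene, Pearson correlation between the alteration predictor and the
#' expression Z-score across paired non-missing samples. For `track =
#' "CNA"` the five-level call (-2..2) is the numeric predictor; for `track
#' = "SNA"` the mutated indicator \{0,1\} gives a point-biserial Pearson
#' correlation. FDR (Benjamini-Hochberg) is computed across genes within
#' the cancer type and track; `passes_filter` applies the R-squared cut
#' (30% for CNA, 10% for SNA) together with FDR < `fdr_sig`. Genes with
#' fewer than 3 paired observations or a constant predictor are kept as
#' rows with `NA` statistics and a `skip_reason`.
#'
#' @param cohort a [cohort_omics()] object with `cna` (or `sna`) and `expr_z`.
#' @param track "CNA" or "SNA".
#' @param thresholds an [analysis_thresholds()] object.
#' @return data.frame(gene, cancer_code, track, n, r, r_squared, p_value,
#'   fdr, passes_filter, skip_reason).
#' @export
correlate_alteration_expression <- function(cohort, track = c("CNA", "SNA"),
                                            thresholds = analysis_thresholds()) {
  track <- match.arg(track)
  stopifnot(inherits(cohort, "cohort_omics"), !is.null(cohort$expr_z))
  pred_m <- if (track == "CNA") cohort$cna else (cohort$sna > 0) * 1
  genes <- cohort$genes
  n <- r <- p <- rep(NA_real_, length(genes))
  reason <- rep(NA_character_, length(genes))
  for (i in seq_along(genes)) {
    x <- as.numeric(pred_m[i, ]); y <- cohort$expr_z[i, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) { reason[i] <- "fewer than 3 paired observations"; next }
    if (sd(x[ok]) == 0) { reason[i] <- "constant predictor"; next }
    if (sd(y[ok]) == 0) { reason[i] <- "constant expression"; next }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    n[i] <- sum(ok); r[i] <- unname(ct$estimate); p[i] <- ct$p.value
  }
  fdr <- rep(NA_real_, length(genes))
  tested <- !is.na(p)
  fdr[tested] <- p.adjust(p[tested], method = "BH")
  r2_cut <- if (track == "CNA") thresholds$r2_cna else thresholds$r2_sna
  data.frame(gene = genes, cancer_code = cohort$cancer_code, track = track,
             n = n, r = r, r_squared = r^2, p_value = p, fdr = fdr,
             passes_filter = !is.na(r) & r^2 > r2_cut &
               !is.na(fdr) & fdr < thresholds$fdr_sig,
             skip_reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan promoter CpGs for expression-methylation correlation (eQTM)
#'
#' Assigns each CpG to genes whose promoter window contains it — on the +
#' strand `[tss - 1000, tss + 500]`, on the - strand the strand-aware flip
#' `[tss - 500, tss + 1000]` — and correlates (Pearson) the CpG's beta
#' values with the gene's expression across shared samples. Expression is
#' `log2(count + 1)` by default; `log_transform = FALSE` correlates raw
#' counts. FDR is Benjamini-Hochberg over all tested (CpG, gene) pairs; per
#' gene, the minimum-p CpG is flagged `is_top_for_gene` (ties broken by
#' cpg_id). CpGs falling in two genes' windows are tested against both.
#'
#' @param methylation list(betas, map) as in [cohort_omics()].
#' @param expr_counts gene x sample raw count matrix.
#' @param annotation compendium annotation (symbol, chromosome, strand, tss).
#' @param window promoter window relative to the TSS in transcription
#'   direction, default c(-1000, 500).
#' @param log_transform correlate log2(count+1) (default) or raw counts.
#' @return data.frame(gene, cpg_id, cpg_position, n, pearson_r, p_value,
#'   fdr, is_top_for_gene).
#' @export
eqtm_scan <- function(methylation, expr_counts, annotation,
                      window = c(-1000, 500), log_transform = TRUE) {
  map <- methylation$map
  betas <- methylation$betas
  expr <- if (log_transform) log2(expr_counts + 1) else expr_counts
  shared <- intersect(colnames(betas), colnames(expr))
  if (length(shared) < 3L) stop("fewer than 3 shared samples", call. = FALSE)
  rows <- list()
  for (gi in seq_len(nrow(annotation))) {
    g <- annotation$symbol[gi]
    if (!g %in% rownames(expr)) next
    tss <- annotation$tss[gi]
    if (annotation$strand[gi] == "+") {
      lo <- tss + window[1]; hi <- tss + window[2]
    } else {
      lo <- tss - window[2]; hi <- tss + -window[1]
    }
    hits <- which(map$chrom == annotation$chromosome[gi] &
                    map$pos >= lo & map$pos <= hi)
    if (length(hits) == 0L) next
    e <- expr[g, shared]
    for (ci in hits) {
      b <- betas[map$cpg_id[ci], shared]
      ok <- !is.na(b) & !is.na(e)
      if (sum(ok) < 3L || sd(b[ok]) == 0 || sd(e[ok]) == 0) next
      ct <- stats::cor.test(b[ok], e[ok], method = "pearson")
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, cpg_id = map$cpg_id[ci],
                   cpg_position = map$pos[ci], n = sum(ok),
                   pearson_r = unname(ct$estimate), p_value = ct$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), cpg_id = character(0),
                      cpg_position = integer(0), n = integer(0),
                      pearson_r = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), is_top_for_gene = logical(0)))
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$gene, res$p_value, res$cpg_id), , drop = FALSE]
  res$is_top_for_gene <- !duplicated(res$gene)
  rownames(res) <- NULL
  res
}
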