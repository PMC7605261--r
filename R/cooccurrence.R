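# Pairwise co-occurrence / mutual exclusivity: per-cancer 2x2 odds ratios
# with the Haldane-Anscombe correction, two-sided Fisher tests, per-cancer
# BH FDR, and cross-cancer meta-averaging of significant odds ratios.

#' Binary altered matrix for co-occurrence analysis
#'
#' A sample is altered for a gene if it carries any of: at least one
#' nonsynonymous mutation, a fusion, a deep amplification (+2) or a deep
#' deletion (-2).
#'
#' @param cohort a [cohort_omics()] object.
#' @return Logical gene x sample matrix.
#' @export
altered_matrix <- function(cohort) {
  m <- (cohort$sna > 0) | (abs(cohort$cna) == 2)
  if (!is.null(cohort$fusions)) m <- m | (cohort$fusions > 0)
  m
}

# Odds ratio with the Haldane-Anscombe correction: 0.5 is added to all four
# cells if and only if at least one cell is zero.
.haldane_or <- function(n11, n10, n01, n00) {
  if (min(n11, n10, n01, n00) == 0) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  (n11 * n00) / (n10 * n01)
}

#' Association statistics for one 2x2 alteration table
#'
#' The unit computation behind [pairwise_association()]: the odds ratio
#' (n11*n00)/(n10*n01) with the Haldane-Anscombe correction (0.5 added to
#' every cell only when some cell is zero) and the two-sided Fisher exact
#' p-value of the uncorrected table.
#'
#' @param n11,n10,n01,n00 2x2 cell counts (both altered / only first / only
#'   second / neither).
#' @return List with `odds_ratio`, `p_value`, `haldane_applied`.
#' @export
pair_table_stats <- function(n11, n10, n01, n00) {
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  list(odds_ratio = .haldane_or(n11, n10, n01, n00),
       p_value = fisher.test(matrix(c(n11, n10, n01, n00), 2L, 2L))$p.value,
       haldane_applied = min(n11, n10, n01, n00) == 0)
}

#' Per-pair per-cancer alteration association
#'
#' For every unordered gene pair, tabulates the 2x2 altered/not-altered
#' sample counts, computes the odds ratio (n11*n00)/(n10*n01) with the
#' Haldane-Anscombe correction applied only when a cell is zero, derives a
#' two-sided Fisher exact p-value from the uncorrected table, and adjusts
#' p-values by Benjamini-Hochberg across all pairs within the cancer type.
#'
#' @param cohort a [cohort_omics()] object.
#' @param genes genes to analyze (default: all; pairs involving genes absent
#'   from the cohort are skipped with a message).
#' @return data.frame(gene_a, gene_b, cancer_code, n11, n10, n01, n00,
#'   odds_ratio, p_value, fdr, cooc_frac, marginal_a, marginal_b).
#' @export
pairwise_association <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "cohort_omics"))
  if (is.null(genes)) genes <- cohort$genes
  absent <- setdiff(genes, cohort$genes)
  if (length(absent) > 0L) {
    message(sprintf("skipping pairs with genes absent from %s: %s",
                    cohort$cancer_code, paste(absent, collapse = ", ")))
    genes <- setdiff(genes, absent)
  }
  if (length(genes) < 2L)
    stop("pairwise association needs at least 2 genes", call. = FALSE)
  alt <- altered_matrix(cohort)[genes, , drop = FALSE]
  n <- ncol(alt)
  pairs <- combn(sort(genes), 2L)
  k <- ncol(pairs)
  n11 <- n10 <- n01 <- n00 <- integer(k)
  or <- p <- numeric(k)
  storage.mode(alt) <- "integer"
  both <- alt %*% t(alt) # n11 for every pair at once
  marg <- rowSums(alt)
  for (j in seq_len(k)) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    n11[j] <- both[a, b]
    n10[j] <- marg[a] - n11[j]
    n01[j] <- marg[b] - n11[j]
    n00[j] <- n - n11[j] - n10[j] - n01[j]
    st <- pair_table_stats(n11[j], n10[j], n01[j], n00[j])
    or[j] <- st$odds_ratio
    p[j] <- st$p_value
  }
  data.frame(gene_a = pairs[1L, ], gene_b = pairs[2L, ],
             cancer_code = cohort$cancer_code,
             n11 = n11, n10 = n10, n01 = n01, n00 = n00,
             odds_ratio = or, p_value = p,
             fdr = p.adjust(p, method = "BH"),
             cooc_frac = n11 / n,
             marginal_a = (n11 + n10) / n, marginal_b = (n11 + n01) / n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-cancer meta-analysis of pairwise associations
#'
#' Per pair, keeps the cancers where the association is significant
#' (FDR < `fdr_sig`) and passes the abundance filter: co-occurrence
#' candidates (OR > 1) must have both genes altered together in at least
#' `cooc_min_frac` of that cancer's samples; exclusivity candidates
#' (OR < 1), for which joint alterations are depleted by construction, must
#' instead have each gene's marginal altered fraction at or above the same
#' cut. Surviving odds ratios are averaged (arithmetic mean by default;
#' `or_scale = "log"` gives the geometric mean) and the direction is
#' `cooccur` when all surviving ORs exceed 1, `exclusive` when all are
#' below 1, `mixed` when they disagree, `none` when no cancer survives.
#'
#' @param records row-bound [pairwise_association()] output across cancers.
#' @param thresholds an [analysis_thresholds()] object (`cooc_min_frac`
#'   0.05 or 0.10 depending on the analysis).
#' @param or_scale "natural" (arithmetic mean of ORs) or "log" (geometric).
#' @return data.frame(gene_a, gene_b, n_significant_cancers,
#'   mean_significant_or, direction).
#' @export
meta_cooccurrence <- function(records, thresholds = analysis_thresholds(),
                              or_scale = c("natural", "log")) {
  or_scale <- match.arg(or_scale)
  dt <- as.data.table(records)
  fmin <- thresholds$cooc_min_frac
  dt[, keep := fdr < thresholds$fdr_sig &
       ((odds_ratio > 1 & cooc_frac >= fmin) |
        (odds_ratio < 1 & marginal_a >= fmin & marginal_b >= fmin))]
  meta <- dt[, {
    sig <- which(keep)
    ors <- odds_ratio[sig]
    dir <- if (length(ors) == 0L) "none"
    else if (all(ors > 1)) "cooccur"
    else if (all(ors < 1)) "exclusive"
    else "mixed"
    mo <- if (length(ors) == 0L) NA_real_
    else if (or_scale == "natural") mean(ors) else exp(mean(log(ors)))
    .(n_significant_cancers = length(ors), mean_significant_or = mo,
      direction = dir)
  }, by = .(gene_a, gene_b)]
  setorderv(meta, c("gene_a", "gene_b"))
  as.data.frame(meta)
}
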