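# Differential expression plumbing: a self-contained negative-binomial Wald
# test (so the pipeline runs without an external DE tool — it is a declared
# built-in, not a DESeq2/edgeR re-implementation), the post-processing
# filters, and the up/down proportion test.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio of
#' each sample's count to the row-wise geometric mean, computed over genes
#' expressed in every sample.
#'
#' @param counts gene x sample count matrix.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- exp(rowMeans(lg))
  ok <- is.finite(ref) & ref > 0
  if (!any(ok)) stop("no gene is expressed in every sample", call. = FALSE)
  apply(counts[ok, , drop = FALSE], 2, function(x) median(x / ref[ok]))
}

#' Built-in tumor-vs-normal negative-binomial Wald test
#'
#' Normalizes both matrices by median-of-ratios size factors, estimates
#' per-gene group means and a method-of-moments dispersion
#' (var = mu + phi mu^2, pooled over groups, floored at 1e-8), and tests the
#' log fold change with a Wald statistic using
#' Var(log mu_hat) ~ (1/mu + phi)/n per group. Fold changes are reported in
#' both log2 and log10. Output metadata (attribute `method`) records that
#' this is the package's built-in test.
#'
#' @param tumor_counts,normal_counts gene x sample count matrices sharing
#'   the gene axis.
#' @return data.frame(gene, total_reads, base_mean, log2_fc, log10_fc,
#'   pvalue, fdr) with attribute `method`.
#' @export
nb_wald_de <- function(tumor_counts, normal_counts) {
  stopifnot(identical(rownames(tumor_counts), rownames(normal_counts)))
  all_counts <- cbind(tumor_counts, normal_counts)
  sf <- size_factors(all_counts)
  norm <- sweep(all_counts, 2, sf, "/")
  nt <- ncol(tumor_counts); nn <- ncol(normal_counts)
  tm <- norm[, seq_len(nt), drop = FALSE]
  nm <- norm[, nt + seq_len(nn), drop = FALSE]
  mu1 <- rowMeans(tm); mu0 <- rowMeans(nm)
  v1 <- apply(tm, 1, stats::var); v0 <- apply(nm, 1, stats::var)
  phi <- ((v1 - mu1) * (nt - 1) + (v0 - mu0) * (nn - 1)) /
    (mu1^2 * (nt - 1) + mu0^2 * (nn - 1))
  phi <- pmax(phi, 1e-8)
  eps <- 0.5
  lfc2 <- log2(mu1 + eps) - log2(mu0 + eps)
  se_log <- sqrt((1 / pmax(mu1, eps) + phi) / nt +
                 (1 / pmax(mu0, eps) + phi) / nn)
  z <- (log(mu1 + eps) - log(mu0 + eps)) / se_log
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(gene = rownames(all_counts),
                    total_reads = rowSums(all_counts),
                    base_mean = rowMeans(norm),
                    log2_fc = lfc2,
                    log10_fc = lfc2 * log10(2),
                    pvalue = p,
                    fdr = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "method") <- "built-in NB Wald (method-of-moments dispersion)"
  res
}

#' Filter a differential-expression table
#'
#' Removes genes with total read coverage below `de_min_reads` (10), with
#' |log10 FC| at or below `logfc_cut`, or with FDR at or above `de_fdr`, and
#' counts the surviving up- (log FC > 0) and down-regulated genes.
#'
#' @param de_table data.frame with columns gene, total_reads, log10_fc, fdr
#'   (e.g. [nb_wald_de()] output or an external tool's table).
#' @param thresholds an [analysis_thresholds()] object.
#' @return List with `table` (surviving rows), `n_up`, `n_down`.
#' @export
de_postprocess <- function(de_table, thresholds = analysis_thresholds()) {
  req <- c("gene", "total_reads", "log10_fc", "fdr")
  miss <- setdiff(req, names(de_table))
  if (length(miss) > 0L)
    stop(sprintf("DE table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  keep <- de_table$total_reads >= thresholds$de_min_reads &
    abs(de_table$log10_fc) > thresholds$logfc_cut &
    de_table$fdr < thresholds$de_fdr
  keep[is.na(keep)] <- FALSE
  tab <- de_table[keep, , drop = FALSE]
  list(table = tab,
       n_up = sum(tab$log10_fc > 0),
       n_down = sum(tab$log10_fc < 0))
}

#' Two-sample test of up- versus down-regulation proportions
#'
#' Pooled two-proportion z-test comparing the up-regulated fraction
#' up/(up+down) between two gene sets (e.g. ERGs versus all genes):
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with the pooled p, two-sided
#' p-value from the normal reference. `mode = "one-sample"` instead tests
#' group 1's up fraction against 0.5 with an exact binomial test.
#'
#' @param up1,down1 up/down counts in group 1.
#' @param up2,down2 up/down counts in group 2 (ignored in one-sample mode).
#' @param mode "two-sample" (default) or "one-sample".
#' @return List with `z` and `p` (z is NA in one-sample mode).
#' @export
updown_proportion_test <- function(up1, down1, up2 = NULL, down2 = NULL,
                                   mode = c("two-sample", "one-sample")) {
  mode <- match.arg(mode)
  stopifnot(up1 >= 0, down1 >= 0)
  n1 <- up1 + down1
  if (n1 == 0) stop("group 1 has zero total", call. = FALSE)
  if (mode == "one-sample") {
    bt <- stats::binom.test(up1, n1, p = 0.5)
    return(list(z = NA_real_, p = bt$p.value))
  }
  stopifnot(!is.null(up2), !is.null(down2), up2 >= 0, down2 >= 0)
  n2 <- up2 + down2
  if (n2 == 0) stop("group 2 has zero total", call. = FALSE)
  p1 <- up1 / n1; p2 <- up2 / n2
  pp <- (up1 + up2) / (n1 + n2)
  if (pp == 0 || pp == 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}
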