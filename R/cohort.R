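#' Assemble a per-cancer multi-omics cohort
#'
#' Bundles the gene-by-sample matrices for one cancer type. All gene-indexed
#' matrices must share one gene axis (rownames); sample axes must be
#' consistent within each matrix. Absence of a mutation or CNA call means 0
#' (no alteration); expression and methylation matrices may carry `NA` for
#' genuinely missing measurements.
#'
#' @param cancer_code short cancer-type label (TCGA-style, e.g. "LUAD").
#' @param sna gene x sample nonnegative integer matrix of nonsynonymous
#'   mutation counts.
#' @param cna gene x sample matrix of GISTIC-style calls in \{-2,-1,0,1,2\}
#'   (-2 deep deletion, -1 shallow loss, +1 shallow gain, +2 deep
#'   amplification).
#' @param expr_z gene x sample matrix of expression Z-scores (optional).
#' @param fusions optional gene x sample logical matrix of fusion calls.
#' @param tumor_counts,normal_counts optional gene x sample raw read-count
#'   matrices (normal tissue optional).
#' @param methylation optional list with `betas` (CpG x sample matrix of
#'   beta values in [0,1]) and `map` (data.frame cpg_id, chrom, pos).
#' @param metastasis optional per-sample factor/character in \{M0, M1, NA\}.
#'
#' @return Object of class `cohort_omics`.
#' @export
cohort_omics <- function(cancer_code, sna, cna, expr_z = NULL, fusions = NULL,
                         tumor_counts = NULL, normal_counts = NULL,
                         methylation = NULL, metastasis = NULL) {
  stopifnot(is.character(cancer_code), length(cancer_code) == 1L)
  .check_gene_matrix(sna, "sna")
  .check_gene_matrix(cna, "cna")
  if (any(sna < 0, na.rm = TRUE)) stop("sna counts must be nonnegative", call. = FALSE)
  bad <- !(cna %in% c(-2L, -1L, 0L, 1L, 2L))
  if (any(bad)) stop("cna calls must be in {-2,-1,0,1,2}", call. = FALSE)
  genes <- rownames(sna)
  for (nm in c("cna", "expr_z", "fusions", "tumor_counts")) {
    m <- get(nm)
    if (!is.null(m) && !identical(rownames(m), genes))
      stop(sprintf("matrix '%s' does not share the gene axis of 'sna'", nm),
           call. = FALSE)
  }
  if (!is.null(methylation)) {
    stopifnot(is.list(methylation), all(c("betas", "map") %in% names(methylation)))
    b <- methylation$betas
    if (any(b < 0 | b > 1, na.rm = TRUE))
      stop("methylation betas must lie in [0, 1]", call. = FALSE)
    stopifnot(identical(rownames(b), as.character(methylation$map$cpg_id)))
  }
  samples <- colnames(sna)
  if (!is.null(metastasis)) {
    metastasis <- as.character(metastasis)
    stopifnot(length(metastasis) == length(samples))
    if (!all(metastasis %in% c("M0", "M1") | is.na(metastasis)))
      stop("metastasis labels must be M0, M1 or NA", call. = FALSE)
  }
  structure(list(cancer_code = cancer_code, samples = samples, genes = genes,
                 sna = sna, cna = cna, expr_z = expr_z, fusions = fusions,
                 tumor_counts = tumor_counts, normal_counts = normal_counts,
                 methylation = methylation, metastasis = metastasis),
            class = "cohort_omics")
}

.check_gene_matrix <- function(m, name) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("'%s' must be a matrix with gene rownames and sample colnames",
                 name), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.cohort_omics <- function(x, ...) {
  cat(sprintf("<cohort_omics> %s: %d genes x %d samples\n",
              x$cancer_code, length(x$genes), length(x$samples)))
  have <- names(x)[!vapply(x, is.null, logical(1))]
  cat("  tracks:", paste(setdiff(have, c("cancer_code", "samples", "genes")),
                         collapse = ", "), "\n")
  invisible(x)
}
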