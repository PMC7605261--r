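#' @importFrom data.table fread fwrite as.data.table data.table setorderv :=
#' @importFrom stats p.adjust cor fisher.test pnorm qnorm rnbinom rnorm rbinom
#'   rgeom runif rgamma rmultinom median mad sd quantile complete.cases setNames
#' @importFrom utils combn head
NULL

#' Default nonsynonymous variant classification stems
#'
#' A mutation record counts as nonsynonymous when its variant classification
#' starts with one of these stems (case-insensitive), so both plain labels
#' ("Missense") and MAF-style labels ("Missense_Mutation",
#' "Frame_Shift_Del") match. Silent/synonymous classes never match.
#'
#' @return Character vector of class stems.
#' @export
nonsynonymous_classes <- function() {
  c("Missense", "Nonsense", "Frame_Shift", "Splice_Site", "In_Frame",
    "Translation_Start_Site", "Nonstop")
}

#' Read a minimal mutation table into a gene x sample count matrix
#'
#' Expects a MAF-minimal TSV with gene symbol, sample barcode and variant
#' classification columns. Counts the nonsynonymous records per (gene,
#' sample); synonymous/silent records are dropped. Genes are sorted
#' lexicographically; samples keep first-appearance order.
#'
#' @param path TSV file path.
#' @param gene_col,sample_col,class_col column names (MAF defaults).
#' @param nonsyn_classes character vector of classification stems counted as
#'   nonsynonymous (prefix match, case-insensitive).
#' @return Integer matrix of mutation counts (possibly 0 x 0 for an
#'   empty table, with a warning).
#' @export
read_mutation_table <- function(path,
                                gene_col = "Hugo_Symbol",
                                sample_col = "Tumor_Sample_Barcode",
                                class_col = "Variant_Classification",
                                nonsyn_classes = nonsynonymous_classes()) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  for (col in c(gene_col, sample_col, class_col)) {
    if (!col %in% names(dt))
      stop(sprintf("mutation table '%s' lacks required column '%s'", path, col),
           call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    warning(sprintf("mutation table '%s' has no records; returning 0 x 0 matrix",
                    path))
    return(matrix(0L, 0, 0))
  }
  cls <- tolower(dt[[class_col]])
  stems <- tolower(nonsyn_classes)
  keep <- vapply(cls, function(x) any(startsWith(x, stems)), logical(1),
                 USE.NAMES = FALSE)
  genes <- sort(unique(dt[[gene_col]]))
  samples <- unique(dt[[sample_col]])
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (any(keep)) {
    tab <- table(factor(dt[[gene_col]][keep], levels = genes),
                 factor(dt[[sample_col]][keep], levels = samples))
    m[] <- as.integer(tab)
  }
  m
}

.read_gene_matrix <- function(path, what) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 1L)
    stop(sprintf("%s matrix '%s' is empty", what, path), call. = FALSE)
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes))
    stop(sprintf("%s matrix '%s' has duplicate gene rows: %s", what, path,
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")),
         call. = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m[order(genes), , drop = FALSE]
}

#' Read a GISTIC-style gene-level CNA call matrix
#'
#' First column holds gene symbols, remaining columns samples; cells must be
#' integers in \{-2,-1,0,1,2\}. Duplicate gene rows and out-of-code values
#' are rejected.
#'
#' @param path TSV file path.
#' @return Integer matrix of CNA calls.
#' @export
read_cna_matrix <- function(path) {
  m <- .read_gene_matrix(path, "CNA")
  bad <- which(!(m %in% c(-2, -1, 0, 1, 2)) | is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("CNA matrix '%s': value %s at gene '%s', sample '%s' is outside {-2..2}",
                 path, m[i, j], rownames(m)[i], colnames(m)[j]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Read expression Z-score and raw count matrices
#'
#' Both files share the CNA-matrix layout (gene column then sample columns).
#' `NA` cells are preserved as missing, never coerced to zero. Negative
#' counts are rejected.
#'
#' @param z_path path to the Z-score TSV (or NULL to skip).
#' @param counts_path path to the raw-count TSV (or NULL to skip).
#' @return List with elements `z` and `counts` (either may be NULL).
#' @export
read_expression_tables <- function(z_path = NULL, counts_path = NULL) {
  z <- if (!is.null(z_path)) .read_gene_matrix(z_path, "Z-score") else NULL
  counts <- NULL
  if (!is.null(counts_path)) {
    counts <- .read_gene_matrix(counts_path, "count")
    bad <- which(counts < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("count matrix '%s': negative count at gene '%s', sample '%s'",
                   counts_path, rownames(counts)[bad[1, 1]],
                   colnames(counts)[bad[1, 2]]), call. = FALSE)
  }
  list(z = z, counts = counts)
}

#' Read a CpG methylation beta table
#'
#' Layout: cpg_id, chrom, pos, then one column per sample with beta values
#' in [0,1] (NA allowed).
#'
#' @param path TSV file path.
#' @return List with `betas` (CpG x sample matrix) and `map`
#'   (data.frame cpg_id, chrom, pos).
#' @export
read_methylation_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  for (col in c("cpg_id", "chrom", "pos"))
    if (!col %in% names(dt))
      stop(sprintf("methylation table '%s' lacks column '%s'", path, col),
           call. = FALSE)
  map <- data.frame(cpg_id = as.character(dt$cpg_id),
                    chrom = as.character(dt$chrom),
                    pos = as.integer(dt$pos), stringsAsFactors = FALSE)
  b <- as.matrix(dt[, -(1:3), drop = FALSE])
  storage.mode(b) <- "double"
  rownames(b) <- map$cpg_id
  if (any(b < 0 | b > 1, na.rm = TRUE))
    stop(sprintf("methylation table '%s' has beta values outside [0,1]", path),
         call. = FALSE)
  list(betas = b, map = map)
}

#' Read the ERG compendium annotation table
#'
#' Required columns: symbol, chromosome, strand, tss, erg_class. Optional:
#' hallmarks (comma-separated labels), tsg_flag, oncogene_flag. Unknown
#' functional classes and duplicated symbols are rejected with the
#' offending rows named.
#'
#' @param path TSV file path.
#' @return data.frame of validated gene annotations; `hallmarks` is a list
#'   column of character vectors.
#' @export
read_compendium <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  req <- c("symbol", "chromosome", "strand", "tss", "erg_class")
  for (col in req)
    if (!col %in% names(dt))
      stop(sprintf("compendium '%s' lacks column '%s'", path, col), call. = FALSE)
  ann <- data.frame(symbol = dt$symbol, chromosome = dt$chromosome,
                    strand = dt$strand, tss = as.integer(dt$tss),
                    erg_class = dt$erg_class, stringsAsFactors = FALSE)
  dup <- unique(ann$symbol[duplicated(ann$symbol)])
  if (length(dup) > 0L)
    stop(sprintf("compendium '%s' has duplicate symbols: %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  bad <- which(!ann$erg_class %in% erg_classes())
  if (length(bad) > 0L)
    stop(sprintf("compendium '%s' row %d (symbol %s): unknown erg_class '%s'",
                 path, bad[1], ann$symbol[bad[1]], ann$erg_class[bad[1]]),
         call. = FALSE)
  bad <- which(!ann$strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop(sprintf("compendium '%s' row %d (symbol %s): strand must be + or -",
                 path, bad[1], ann$symbol[bad[1]]), call. = FALSE)
  bad <- which(is.na(ann$tss) | ann$tss < 1L)
  if (length(bad) > 0L)
    stop(sprintf("compendium '%s' row %d (symbol %s): tss must be >= 1",
                 path, bad[1], ann$symbol[bad[1]]), call. = FALSE)
  bad <- which(!ann$chromosome %in% c(as.character(1:22), "X", "Y"))
  if (length(bad) > 0L)
    stop(sprintf("compendium '%s' row %d (symbol %s): chromosome '%s' not in 1..22, X, Y",
                 path, bad[1], ann$symbol[bad[1]], ann$chromosome[bad[1]]),
         call. = FALSE)
  ann$hallmarks <- if ("hallmarks" %in% names(dt)) {
    lapply(strsplit(ifelse(is.na(dt$hallmarks), "", dt$hallmarks), ","),
           function(x) x[nzchar(x)])
  } else rep(list(character(0)), nrow(ann))
  ann$tsg_flag <- if ("tsg_flag" %in% names(dt)) as.logical(dt$tsg_flag) else FALSE
  ann$oncogene_flag <- if ("oncogene_flag" %in% names(dt)) as.logical(dt$oncogene_flag) else FALSE
  ann[order(ann$symbol), , drop = FALSE]
}

#' Write a result table to TSV
#'
#' Deterministic output: columns in their given order, rows sorted by the
#' identifier (character/factor) columns, NA written as an empty field.
#' Numeric values are written with round-trip accuracy so that reading the
#' file back restores the table.
#'
#' @param records data.frame / data.table sharing one field schema.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_result_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  dt <- as.data.table(records)
  idcols <- names(dt)[vapply(dt, function(x) is.character(x) || is.factor(x),
                             logical(1))]
  if (nrow(dt) > 0L && length(idcols) > 0L) setorderv(dt, idcols)
  fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV path.
#' @return data.frame with empty fields restored as NA.
#' @export
read_result_table <- function(path) {
  as.data.frame(fread(path, sep = "\t", header = TRUE, na.strings = ""))
}

#' Write a gene x sample matrix in the CNA/Z-score TSV dialect
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param gene_col name of the first (gene) column.
#' @return Invisibly, the path.
#' @export
write_gene_matrix <- function(m, path, gene_col = "gene") {
  dt <- data.table(gene = rownames(m))
  setnames_safe <- function(x, nm) { names(x)[1] <- nm; x }
  dt <- setnames_safe(dt, gene_col)
  out <- cbind(dt, as.data.table(m))
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a CRISPR guide library table
#'
#' Columns: guide_id, gene, spacer (20-nt, A/C/G/T). Duplicate spacers or
#' guide ids are rejected; genes must carry 1-4 guides.
#'
#' @param path TSV path.
#' @return data.frame with guide_id, gene, spacer.
#' @export
read_guide_library <- function(path) {
  dt <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                            colClasses = "character"))
  for (col in c("guide_id", "gene", "spacer"))
    if (!col %in% names(dt))
      stop(sprintf("guide library '%s' lacks column '%s'", path, col),
           call. = FALSE)
  validate_guide_library(dt)
  dt
}

#' Validate a guide library data.frame
#' @param lib data.frame with guide_id, gene, spacer.
#' @return Invisibly TRUE; errors on violation.
#' @export
validate_guide_library <- function(lib) {
  if (anyDuplicated(lib$spacer))
    stop("guide library has duplicate spacers", call. = FALSE)
  if (anyDuplicated(lib$guide_id))
    stop("guide library has duplicate guide ids", call. = FALSE)
  if (!all(grepl("^[ACGT]+$", lib$spacer)))
    stop("spacers must be sequences over {A,C,G,T}", call. = FALSE)
  if (!all(nchar(lib$spacer) == 20L))
    stop("spacers must be 20-mers", call. = FALSE)
  gpg <- table(lib$gene)
  if (any(gpg < 1L | gpg > 4L))
    stop("each gene must carry 1-4 guides", call. = FALSE)
  invisible(TRUE)
}

#' Read a guide x condition screen count matrix
#' @param path TSV path; first column guide_id, remaining columns conditions.
#' @return Integer matrix of counts.
#' @export
read_screen_counts <- function(path) {
  m <- .read_gene_matrix(path, "screen count")
  if (any(m < 0 | m != round(m), na.rm = TRUE))
    stop(sprintf("screen counts '%s' must be nonnegative integers", path),
         call. = FALSE)
  storage.mode(m) <- "integer"
  m
}
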