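# Pooled CRISPR screen analysis: spacer counting from FASTQ, library QC,
# a robust per-guide enrichment/depletion test, cross-method and
# cross-timepoint consensus hit-calling, and the metastatic-vs-nonmetastatic
# mutation comparison for hit genes.

# Structural FASTQ check (record framing only; sequence parsing is left to
# Biostrings, which accepts truncated records silently).
.validate_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': truncated record %d", path,
                 n %/% 4L + 1L), call. = FALSE)
  idx <- seq_len(n %/% 4L)
  bad_hdr <- which(!startsWith(lines[4L * idx - 3L], "@"))
  bad_sep <- which(!startsWith(lines[4L * idx - 1L], "+"))
  bad_len <- which(nchar(lines[4L * idx - 2L]) != nchar(lines[4L * idx]))
  bad <- c(bad_hdr, bad_sep, bad_len)
  if (length(bad) > 0L)
    stop(sprintf("malformed FASTQ '%s': record %d", path, min(bad)),
         call. = FALSE)
  invisible(TRUE)
}

#' Count guide spacers in amplicon FASTQ files
#'
#' A read is assigned to a guide when the guide's 20-nt spacer occurs as a
#' substring of the read (as-sequenced orientation; optionally also the
#' reverse complement) within at most `max_mismatch` mismatches. Reads
#' matching more than one guide are discarded as ambiguous; accounting is
#' conserved: mapped + ambiguous + unmapped = total per file.
#'
#' @param fastq_paths named character vector of FASTQ paths; names become
#'   condition labels (file names without extension when unnamed).
#' @param library guide library data.frame (guide_id, gene, spacer).
#' @param max_mismatch maximum mismatches allowed in a spacer match
#'   (default 0, exact).
#' @param reverse_complement also search the reverse-complemented spacer.
#' @return List with `counts` (guide x condition integer matrix) and
#'   `stats` (data.frame condition, total, mapped, ambiguous, unmapped).
#' @export
count_guides_from_fastq <- function(fastq_paths, library, max_mismatch = 0,
                                    reverse_complement = FALSE) {
  validate_guide_library(library)
  if (is.null(names(fastq_paths)) || any(!nzchar(names(fastq_paths))))
    names(fastq_paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_paths))
  spacers <- Biostrings::DNAStringSet(library$spacer)
  names(spacers) <- library$guide_id
  counts <- matrix(0L, nrow(library), length(fastq_paths),
                   dimnames = list(library$guide_id, names(fastq_paths)))
  stats <- data.frame(condition = names(fastq_paths), total = 0L,
                      mapped = 0L, ambiguous = 0L, unmapped = 0L,
                      stringsAsFactors = FALSE)
  for (k in seq_along(fastq_paths)) {
    .validate_fastq(fastq_paths[k])
    reads <- tryCatch(
      Biostrings::readDNAStringSet(fastq_paths[k], format = "fastq"),
      error = function(e) stop(sprintf("malformed FASTQ '%s': %s",
                                       fastq_paths[k], conditionMessage(e)),
                               call. = FALSE))
    nmatch <- matrix(0L, length(reads), nrow(library))
    if (max_mismatch == 0 && !reverse_complement) {
      pd <- Biostrings::PDict(spacers)
      hits <- Biostrings::vwhichPDict(pd, reads)
      lens <- lengths(hits)
      idx <- cbind(rep(seq_along(reads), lens), unlist(hits))
      if (nrow(idx) > 0) nmatch[idx] <- 1L
    } else {
      for (g in seq_len(nrow(library))) {
        hit <- Biostrings::vcountPattern(spacers[[g]], reads,
                                         max.mismatch = max_mismatch) > 0
        if (reverse_complement)
          hit <- hit | Biostrings::vcountPattern(
            Biostrings::reverseComplement(spacers[[g]]), reads,
            max.mismatch = max_mismatch) > 0
        nmatch[hit, g] <- 1L
      }
    }
    per_read <- rowSums(nmatch)
    uniq <- per_read == 1L
    if (any(uniq)) {
      assigned <- max.col(nmatch[uniq, , drop = FALSE])
      tab <- tabulate(assigned, nbins = nrow(library))
      counts[, k] <- as.integer(tab)
    }
    stats$total[k] <- length(reads)
    stats$mapped[k] <- sum(uniq)
    stats$ambiguous[k] <- sum(per_read > 1L)
    stats$unmapped[k] <- sum(per_read == 0L)
  }
  list(counts = counts, stats = stats)
}

#' Library representation QC
#'
#' Coverage summary of one baseline condition: mean/median per-guide
#' coverage, fraction of guides with zero counts, the 90th/10th percentile
#' skew ratio, and the Gini coefficient of the count distribution.
#'
#' @param counts guide x condition count matrix.
#' @param baseline condition column to QC (default the first).
#' @param target_coverage intended mean reads per guide (reported alongside
#'   the achieved mean; NA to skip).
#' @return One-row data.frame of QC statistics.
#' @export
library_representation <- function(counts, baseline = colnames(counts)[1],
                                   target_coverage = NA_real_) {
  if (is.null(counts) || nrow(counts) == 0L)
    stop("empty count matrix", call. = FALSE)
  x <- counts[, baseline]
  qs <- quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  xs <- sort(x)
  k <- length(xs)
  gini <- if (sum(xs) == 0) 0 else
    sum((2 * seq_len(k) - k - 1) * xs) / (k * sum(xs))
  data.frame(condition = baseline, n_guides = k,
             mean_coverage = mean(x), median_coverage = median(x),
             target_coverage = target_coverage,
             zero_frac = mean(x == 0),
             skew_ratio_90_10 = if (qs[1] > 0) qs[2] / qs[1] else Inf,
             gini = gini, row.names = NULL, stringsAsFactors = FALSE)
}

#' Robust per-guide enrichment/depletion test
#'
#' Self-contained guide test (a declared substitute for external count-model
#' tools, not a re-implementation of them): counts are normalized by
#' median-of-ratios size factors over the two compared conditions, the
#' per-guide log2 ratio (late over early, +0.5 pseudocount) is standardized
#' against the library-wide median and MAD — under the screen null most
#' guides are unchanged, so the bulk calibrates the scale — and a two-sided
#' p-value is taken from the normal reference, with BH adjustment across
#' guides.
#'
#' @param counts guide x condition count matrix.
#' @param comparison list or character vector with elements `late` and
#'   `early` naming the compared condition columns.
#' @param library optional guide library to attach gene names.
#' @return data.frame(guide_id, gene, log2_ratio, z, p_value, fdr,
#'   direction).
#' @export
test_guides <- function(counts, comparison, library = NULL) {
  late <- comparison[["late"]]; early <- comparison[["early"]]
  missing_cond <- setdiff(c(late, early), colnames(counts))
  if (length(missing_cond) > 0L)
    stop(sprintf("comparison names missing condition(s): %s",
                 paste(missing_cond, collapse = ", ")), call. = FALSE)
  sub <- counts[, c(early, late), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  lr <- log2(norm[, 2] + 0.5) - log2(norm[, 1] + 0.5)
  # precision weighting: delta-method sampling sd of the log2 ratio, so
  # low-abundance guides are not over-called relative to the library bulk
  samp_sd <- sqrt(1 / (sub[, 1] + 0.5) + 1 / (sub[, 2] + 0.5)) / log(2)
  t_stat <- (lr - median(lr)) / samp_sd
  s <- mad(t_stat) # rescale to the bulk: most guides are unchanged
  if (s == 0) s <- 1e-8
  z <- t_stat / s
  z[lr == median(lr)] <- 0
  p <- 2 * pnorm(-abs(z))
  gene <- if (!is.null(library))
    library$gene[match(rownames(counts), library$guide_id)] else NA_character_
  data.frame(guide_id = rownames(counts), gene = gene,
             log2_ratio = lr, z = z, p_value = p,
             fdr = p.adjust(p, method = "BH"),
             direction = ifelse(lr >= 0, "enriched", "depleted"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-method, cross-timepoint consensus hit-calling
#'
#' A guide is a consensus hit for a comparison when every supplied method
#' calls it below that method's p-value threshold with one consistent
#' direction. A gene is a candidate when at least one of its guides
#' (`min_guides` to require more) is a consensus hit in every required
#' comparison, with the same direction throughout; genes whose consensus
#' guides disagree in direction across comparisons are reported with
#' direction `mixed` and excluded from candidates. Venn-style intersection
#' counts of consensus guides across comparisons are also returned.
#'
#' @param per_method_calls data.frame with columns method, comparison,
#'   guide_id, gene, p_value, direction (row-bound [test_guides()] outputs
#'   or external per-guide tables).
#' @param required_comparisons comparisons a candidate gene must pass in
#'   (default: all present).
#' @param method_thresholds named numeric vector of per-method p cuts
#'   (defaults to `analysis_thresholds()$screen_p` matched by position when
#'   names differ).
#' @param min_guides minimum consensus guides per gene per comparison.
#' @return List with `guide_hits`, `gene_calls`, `candidates` (character
#'   vector) and `venn_counts`.
#' @export
consensus_hits <- function(per_method_calls,
                           required_comparisons = NULL,
                           method_thresholds = NULL,
                           min_guides = 1L) {
  calls <- as.data.table(per_method_calls)
  req <- c("method", "comparison", "guide_id", "gene", "p_value", "direction")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0L)
    stop(sprintf("per-method calls lack column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  methods <- sort(unique(calls$method))
  if (is.null(method_thresholds)) {
    sp <- analysis_thresholds()$screen_p
    method_thresholds <- setNames(rep_len(unname(sp), length(methods)), methods)
  }
  if (!all(methods %in% names(method_thresholds)))
    stop("every method needs a p-value threshold", call. = FALSE)
  if (is.null(required_comparisons))
    required_comparisons <- sort(unique(calls$comparison))

  if (length(methods) > 1L) {
    shared <- Reduce(intersect,
                     lapply(methods, function(m) calls$guide_id[calls$method == m]))
    if (length(shared) == 0L)
      stop("no overlapping guides between the methods' tables", call. = FALSE)
  }

  calls[, pass := p_value < method_thresholds[method]]
  guide_hits <- calls[, {
    n_m <- length(unique(method))
    ok <- n_m == length(methods) && all(pass) &&
      length(unique(direction)) == 1L
    .(consensus = ok,
      direction = if (ok) direction[1] else NA_character_)
  }, by = .(comparison, guide_id, gene)]

  hits <- guide_hits[consensus == TRUE]
  gene_calls <- hits[comparison %in% required_comparisons, {
    by_comp <- split(direction, comparison)
    covered <- length(by_comp) == length(required_comparisons)
    dirs <- unique(direction)
    n_min <- if (covered) min(vapply(by_comp, length, integer(1))) else 0L
    .(n_comparisons = length(by_comp),
      direction = if (length(dirs) == 1L) dirs else "mixed",
      candidate = covered && length(dirs) == 1L && n_min >= min_guides)
  }, by = .(gene)]

  venn <- hits[comparison %in% required_comparisons,
               .(pattern = paste(sort(unique(comparison)), collapse = "&")),
               by = .(guide_id)][, .(n_guides = .N), by = .(pattern)]
  setorderv(venn, "pattern")

  list(guide_hits = as.data.frame(guide_hits),
       gene_calls = as.data.frame(gene_calls[order(gene)]),
       candidates = sort(gene_calls$gene[gene_calls$candidate]),
       venn_counts = as.data.frame(venn))
}

#' Mutation frequency of hit genes in metastatic vs nonmetastatic samples
#'
#' Per cancer type, computes each gene's mutated-sample fraction among
#' M0-labeled and among M1-labeled samples (unlabeled samples excluded);
#' per gene, the unweighted mean across cancer types contributing at least
#' one sample in both subsets. A pooled Fisher test over the summed counts
#' is reported as exploratory.
#'
#' @param cohorts named list of [cohort_omics()] objects with metastasis
#'   labels.
#' @param gene_set genes to compare (e.g. screen candidates); genes absent
#'   everywhere are skipped with a warning.
#' @return data.frame(gene, n_cancers, mean_pct_M0, mean_pct_M1,
#'   difference, pooled_p_exploratory).
#' @export
metastasis_mutation_comparison <- function(cohorts, gene_set) {
  gene_set <- unique(gene_set)
  all_genes <- Reduce(union, lapply(cohorts, `[[`, "genes"))
  absent <- setdiff(gene_set, all_genes)
  if (length(absent) > 0L) {
    warning(sprintf("genes absent from all cohorts skipped: %s",
                    paste(absent, collapse = ", ")))
    gene_set <- setdiff(gene_set, absent)
  }
  rows <- lapply(gene_set, function(g) {
    p0 <- p1 <- numeric(0)
    m0_mut <- m0_tot <- m1_mut <- m1_tot <- 0L
    for (co in cohorts) {
      if (is.null(co$metastasis) || !g %in% co$genes) next
      lab <- co$metastasis
      i0 <- which(!is.na(lab) & lab == "M0")
      i1 <- which(!is.na(lab) & lab == "M1")
      if (length(i0) == 0L || length(i1) == 0L) next
      mut <- co$sna[g, ] > 0
      p0 <- c(p0, mean(mut[i0])); p1 <- c(p1, mean(mut[i1]))
      m0_mut <- m0_mut + sum(mut[i0]); m0_tot <- m0_tot + length(i0)
      m1_mut <- m1_mut + sum(mut[i1]); m1_tot <- m1_tot + length(i1)
    }
    pooled_p <- if (m0_tot > 0 && m1_tot > 0)
      fisher.test(matrix(c(m1_mut, m1_tot - m1_mut,
                           m0_mut, m0_tot - m0_mut), 2L, 2L))$p.value
    else NA_real_
    data.frame(gene = g, n_cancers = length(p0),
               mean_pct_M0 = if (length(p0) > 0) 100 * mean(p0) else NA_real_,
               mean_pct_M1 = if (length(p1) > 0) 100 * mean(p1) else NA_real_,
               difference = if (length(p0) > 0)
                 100 * (mean(p1) - mean(p0)) else NA_real_,
               pooled_p_exploratory = pooled_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
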