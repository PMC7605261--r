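# Synthetic pooled CRISPR screen: guide library, Dirichlet-multinomial
# counts with planted fold effects, and amplicon FASTQ emission.

#' Build a synthetic CRISPR guide library
#'
#' 1-4 guides per gene with unique random 20-mer spacers, mirroring the
#' structure of a pooled knockout library targeting every compendium gene.
#'
#' @param genes character vector of target genes.
#' @param guides_per_gene integer vector recycled over genes, or NULL to
#'   sample 1-4 per gene.
#' @param seed RNG seed.
#' @return data.frame(guide_id, gene, spacer).
#' @export
make_guide_library <- function(genes, guides_per_gene = NULL, seed = 1L) {
  set.seed(substream_seed(seed, "guide_library"))
  if (is.null(guides_per_gene))
    guides_per_gene <- sample(1:4, length(genes), replace = TRUE)
  gpg <- rep_len(guides_per_gene, length(genes))
  gene <- rep(genes, gpg)
  guide_id <- unlist(lapply(seq_along(genes), function(i)
    sprintf("%s_g%d", genes[i], seq_len(gpg[i]))))
  spacer <- character(length(gene))
  seen <- new.env(hash = TRUE)
  for (i in seq_along(spacer)) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
      if (is.null(seen[[s]])) { seen[[s]] <- TRUE; spacer[i] <- s; break }
    }
  }
  lib <- data.frame(guide_id = guide_id, gene = gene, spacer = spacer,
                    stringsAsFactors = FALSE)
  validate_guide_library(lib)
  lib
}

#' Simulate pooled screen counts and optional amplicon FASTQ files
#'
#' Day-0 guide abundances follow a Dirichlet-multinomial; at later
#' timepoints the proportions of planted guides are multiplied by their fold
#' effects (fold > 1 enrichment, fold < 1 depletion) and renormalized before
#' multinomial sampling at the same depth. When `fastq_dir` is given, one
#' FASTQ file per condition is written, each read embedding the guide's
#' spacer in fixed flanking sequence with read multiplicity equal to the
#' count table, so re-counting the FASTQ reproduces the counts exactly.
#'
#' @param library guide library data.frame ([make_guide_library()]).
#' @param timepoints condition labels; the first is the baseline.
#' @param depth total reads per condition.
#' @param concentration Dirichlet concentration per guide (smaller = more
#'   skewed library).
#' @param planted data.frame(guide_id, fold) of per-timepoint fold effects
#'   applied at every post-baseline timepoint, or NULL.
#' @param fastq_dir directory for FASTQ output, or NULL to skip.
#' @param flank5,flank3 fixed amplicon context around the spacer.
#' @param seed RNG seed.
#' @return List with `counts` (guide x condition integer matrix),
#'   `conditions` (data.frame condition, timepoint), `truth` (planted table
#'   with direction), and `fastq_paths` (named, or NULL).
#' @export
simulate_screen_data <- function(library,
                                 timepoints = c("D0", "D14", "D21", "D28"),
                                 depth = 1e5,
                                 concentration = 3,
                                 planted = NULL,
                                 fastq_dir = NULL,
                                 flank5 = "ACCGGTAGAGGTTCACCGAC",
                                 flank3 = "GTTTTAGAGCTAGAAATAGC",
                                 seed = 1L) {
  validate_guide_library(library)
  g <- nrow(library)
  if (!is.null(planted) && !all(planted$guide_id %in% library$guide_id))
    stop("planted guide ids absent from the library", call. = FALSE)
  set.seed(substream_seed(seed, "screen_counts"))
  alpha <- rep(concentration, g)
  p0 <- rgamma(g, shape = alpha, rate = 1)
  p0 <- p0 / sum(p0)
  counts <- matrix(0L, g, length(timepoints),
                   dimnames = list(library$guide_id, timepoints))
  counts[, 1L] <- as.integer(rmultinom(1, depth, p0))
  fold <- rep(1, g)
  if (!is.null(planted))
    fold[match(planted$guide_id, library$guide_id)] <- planted$fold
  for (k in seq_along(timepoints)[-1L]) {
    pk <- p0 * fold
    pk <- pk / sum(pk)
    counts[, k] <- as.integer(rmultinom(1, depth, pk))
  }
  truth <- NULL
  if (!is.null(planted)) {
    truth <- data.frame(guide_id = planted$guide_id,
                        gene = library$gene[match(planted$guide_id,
                                                  library$guide_id)],
                        fold = planted$fold,
                        direction = ifelse(planted$fold > 1, "enriched",
                                           "depleted"),
                        stringsAsFactors = FALSE)
  }
  fastq_paths <- NULL
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(substream_seed(seed, "screen_fastq"))
    fastq_paths <- setNames(file.path(fastq_dir, paste0(timepoints, ".fastq")),
                            timepoints)
    seqs <- paste0(flank5, library$spacer, flank3)
    qual <- strrep("I", nchar(seqs[1]))
    for (k in seq_along(timepoints)) {
      reads <- rep(seqs, counts[, k])
      reads <- reads[sample.int(length(reads))]
      recs <- character(4L * length(reads))
      idx <- seq_along(reads)
      recs[4L * idx - 3L] <- sprintf("@%s_read%07d", timepoints[k], idx)
      recs[4L * idx - 2L] <- reads
      recs[4L * idx - 1L] <- "+"
      recs[4L * idx] <- qual
      writeLines(recs, fastq_paths[k])
    }
  }
  list(counts = counts,
       conditions = data.frame(condition = timepoints, timepoint = timepoints,
                               stringsAsFactors = FALSE),
       truth = truth, fastq_paths = fastq_paths)
}
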