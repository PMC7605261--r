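# Driver prioritization: the competition-ranking engine, the Pan-Cancer
# Driver score (four weighted track rankings), the percentile-based
# Multi-Omics Driver score, and Fisher set/hallmark enrichment.

#' Competition ranking with the tie-gap rule
#'
#' Ranks qualified genes ascending by the lexicographic (primary, secondary)
#' key. The gene with the lowest key scores 1; x genes tied on both keys at
#' score y all receive y, and the next distinct gene receives y + x
#' (competition / "min" ranking). Unqualified genes carry no score.
#'
#' @param genes character vector of gene names.
#' @param primary_counts nonnegative integers (e.g. number of cancer types
#'   passing the frequency filter).
#' @param secondary_values real tie-breakers (e.g. mean alteration
#'   percentage); NaN is an error.
#' @param qualified logical; defaults to `primary_counts >= 1`.
#' @return data.frame(gene, primary_count, secondary_value, qualified,
#'   ranking_score) with `NA` score for unqualified genes.
#' @export
competition_rank <- function(genes, primary_counts, secondary_values,
                             qualified = NULL) {
  stopifnot(length(genes) == length(primary_counts),
            length(genes) == length(secondary_values))
  if (any(is.nan(secondary_values)))
    stop("secondary values must not be NaN", call. = FALSE)
  if (any(primary_counts < 0, na.rm = TRUE))
    stop("primary counts must be nonnegative", call. = FALSE)
  if (is.null(qualified)) qualified <- primary_counts >= 1
  score <- rep(NA_integer_, length(genes))
  qi <- which(qualified)
  if (length(qi) > 0L) {
    p <- primary_counts[qi]; s <- secondary_values[qi]
    o <- order(p, s)
    ps <- p[o]; ss <- s[o]
    k <- length(o)
    new_grp <- c(TRUE, ps[-1] != ps[-k] | ss[-1] != ss[-k])
    sc <- cummax(ifelse(new_grp, seq_len(k), 0L))
    score[qi[o]] <- as.integer(sc)
  }
  data.frame(gene = genes, primary_count = primary_counts,
             secondary_value = secondary_values, qualified = qualified,
             ranking_score = score, row.names = NULL, stringsAsFactors = FALSE)
}

# Per-track (primary, secondary) statistics across cohorts.
.track_stats <- function(cohorts, thresholds, de_tables = NULL) {
  genes <- sort(Reduce(union, lapply(cohorts, `[[`, "genes")))
  fmin <- thresholds$driver_freq_min_frac
  grab <- function(fun) {
    m <- matrix(NA_real_, length(genes), length(cohorts),
                dimnames = list(genes, names(cohorts)))
    for (j in seq_along(cohorts)) {
      v <- fun(cohorts[[j]])
      m[names(v), j] <- v
    }
    m
  }
  sna_f <- grab(function(co) rowMeans(co$sna > 0))
  amp_f <- grab(function(co) rowMeans(co$cna == 2))
  del_f <- grab(function(co) rowMeans(co$cna == -2))
  z_f <- grab(function(co) {
    if (is.null(co$expr_z)) return(setNames(rep(NA_real_, length(co$genes)),
                                            co$genes))
    nobs <- rowSums(!is.na(co$expr_z))
    ifelse(nobs > 0,
           rowSums(abs(co$expr_z) > thresholds$z_cut, na.rm = TRUE) / nobs,
           NA_real_)
  })

  prim_sec <- function(fr, qual) {
    nq <- rowSums(qual, na.rm = TRUE)
    sec <- ifelse(nq > 0, rowSums(fr * qual, na.rm = TRUE) / nq, 0)
    list(primary = nq, secondary = sec)
  }
  sna <- prim_sec(sna_f, sna_f >= fmin)
  amp <- prim_sec(amp_f, amp_f >= fmin)
  del <- prim_sec(del_f, del_f >= fmin)
  pick_amp <- amp$primary > del$primary |
    (amp$primary == del$primary & amp$secondary >= del$secondary)
  cna <- list(primary = ifelse(pick_amp, amp$primary, del$primary),
              secondary = ifelse(pick_amp, amp$secondary, del$secondary),
              direction = ifelse(pmax(amp$primary, del$primary) == 0,
                                 NA_character_,
                                 ifelse(pick_amp, "amp", "del")))
  zz <- prim_sec(z_f, z_f >= thresholds$z_sample_frac)

  # FC track: external DE tables, or built-in test on cancers with normals
  if (is.null(de_tables)) {
    de_tables <- list()
    for (nm in names(cohorts)) {
      co <- cohorts[[nm]]
      if (!is.null(co$tumor_counts) && !is.null(co$normal_counts))
        de_tables[[nm]] <- nb_wald_de(co$tumor_counts, co$normal_counts)
    }
  }
  fc_prim <- setNames(rep(0, length(genes)), genes)
  fc_sum <- fc_prim
  for (tab in de_tables) {
    qual <- tab$fdr < thresholds$de_fdr &
      abs(tab$log10_fc) > thresholds$logfc_cut
    qual[is.na(qual)] <- FALSE
    g <- intersect(tab$gene[qual], genes)
    fc_prim[g] <- fc_prim[g] + 1
    fc_sum[g] <- fc_sum[g] + abs(tab$log10_fc[qual][match(g, tab$gene[qual])])
  }
  fc <- list(primary = fc_prim,
             secondary = ifelse(fc_prim > 0, fc_sum / fc_prim, 0))
  list(genes = genes, sna = sna, cna = cna, z = zz, fc = fc)
}

#' Pan-Cancer Driver score
#'
#' Four independent competition rankings — SNA, CNA (per deep-CNA
#' direction, the direction with more qualifying cancer types winning, ties
#' by mean frequency), expression Z-score, and tumor-vs-normal fold change —
#' are combined as a weighted sum (weights 1, 1, 0.5, 0.5). For each track
#' the primary key is the number of cancer types in which the gene passes
#' that track's frequency filter (5% of samples for SNA/CNA, 15% of samples
#' with |Z| > 2, FDR < 0.05 with |log10 FC| above the cut for FC) and the
#' secondary key the mean qualifying alteration percentage (mean |log10 FC|
#' for the FC track). Genes unqualified on a track contribute 0 for that
#' track, so single-track drivers remain comparable. The final
#' `pan_cancer_score` is the ordinal position by descending combined sum
#' (1 = strongest; ties share the smaller position).
#'
#' @param cohorts named list of [cohort_omics()] objects.
#' @param thresholds an [analysis_thresholds()] object.
#' @param de_tables optional named list (by cancer code) of DE tables with
#'   columns gene, log10_fc, fdr; when NULL, the built-in [nb_wald_de()] is
#'   run for cohorts carrying both tumor and normal counts, and cancers
#'   without normals contribute no FC counts.
#' @return data.frame with per-track primaries/ranks, cna_direction,
#'   `combined` and `pan_cancer_score` (NA for genes qualified on no track).
#' @export
pan_cancer_driver_score <- function(cohorts, thresholds = analysis_thresholds(),
                                    de_tables = NULL) {
  st <- .track_stats(cohorts, thresholds, de_tables)
  w <- thresholds$weights
  rk <- function(tr) competition_rank(st$genes, tr$primary, tr$secondary)
  r_sna <- rk(st$sna); r_cna <- rk(st$cna); r_z <- rk(st$z); r_fc <- rk(st$fc)
  contrib <- function(r) ifelse(is.na(r$ranking_score), 0, r$ranking_score)
  combined <- w["sna"] * contrib(r_sna) + w["cna"] * contrib(r_cna) +
    w["z"] * contrib(r_z) + w["fc"] * contrib(r_fc)
  any_track <- !is.na(r_sna$ranking_score) | !is.na(r_cna$ranking_score) |
    !is.na(r_z$ranking_score) | !is.na(r_fc$ranking_score)
  if (!any(any_track))
    warning("no gene passes any driver track filter; empty score table")
  pos <- rep(NA_integer_, length(st$genes))
  if (any(any_track)) {
    cb <- combined[any_track]
    pos[any_track] <- as.integer(rank(-cb, ties.method = "min"))
  }
  data.frame(gene = st$genes,
             sna_primary = st$sna$primary, sna_rank = r_sna$ranking_score,
             cna_primary = st$cna$primary, cna_rank = r_cna$ranking_score,
             cna_direction = st$cna$direction,
             z_primary = st$z$primary, z_rank = r_z$ranking_score,
             fc_primary = st$fc$primary, fc_rank = r_fc$ranking_score,
             combined = combined, pan_cancer_score = pos,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-Omics Driver score for one cancer type
#'
#' Equal-weight mean of the within-cancer percentile ranks (rank / n, ties
#' averaged) of three per-gene statistics: mutated-sample fraction, deep
#' CNA fraction (the larger of the two directions), and the fraction of
#' samples with |Z| > `z_cut`. Scores lie in (0, 1]; a gene at the
#' within-cancer maximum of all three tracks scores 1.
#'
#' @param cohort a [cohort_omics()] object with sna, cna and expr_z.
#' @param thresholds an [analysis_thresholds()] object.
#' @return data.frame(gene, cancer_code, sna_frac, deep_cna_frac,
#'   z_aberrant_frac, score).
#' @export
multi_omics_driver_score <- function(cohort, thresholds = analysis_thresholds()) {
  stopifnot(inherits(cohort, "cohort_omics"), !is.null(cohort$expr_z))
  if (length(cohort$genes) < 2L)
    stop("multi-omics scoring needs at least 2 genes", call. = FALSE)
  sna_f <- rowMeans(cohort$sna > 0)
  cna_f <- pmax(rowMeans(cohort$cna == 2), rowMeans(cohort$cna == -2))
  nobs <- rowSums(!is.na(cohort$expr_z))
  z_f <- ifelse(nobs > 0,
                rowSums(abs(cohort$expr_z) > thresholds$z_cut, na.rm = TRUE) / nobs,
                NA_real_)
  pct <- function(x) rank(x, ties.method = "average", na.last = "keep") /
    sum(!is.na(x))
  score <- rowMeans(cbind(pct(sna_f), pct(cna_f), pct(z_f)))
  data.frame(gene = cohort$genes, cancer_code = cohort$cancer_code,
             sna_frac = sna_f, deep_cna_frac = cna_f, z_aberrant_frac = z_f,
             score = score, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher enrichment of a query gene set in a category
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 table implied by the
#' query set, category set and universe; the odds ratio is the sample OR
#' (ad)/(bc) of that table.
#'
#' @param query_set,category_set character vectors, subsets of `universe`.
#' @param universe background gene universe.
#' @param set_name label for the category (e.g. hallmark name).
#' @param adjustment "none", "bonferroni" or "bh".
#' @param n_tests number of tests in the correction family.
#' @return One-row data.frame(set_name, overlap, set_size, universe_size,
#'   category_size, odds_ratio, p_value, adjusted_p, adjustment).
#' @export
set_enrichment_fisher <- function(query_set, category_set, universe,
                                  set_name = "set",
                                  adjustment = c("none", "bonferroni", "bh"),
                                  n_tests = 1L) {
  adjustment <- match.arg(adjustment)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query_set <- intersect(unique(query_set), universe)
  category_set <- intersect(unique(category_set), universe)
  a <- length(intersect(query_set, category_set))
  b <- length(query_set) - a
  cc <- length(category_set) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  or <- (a * d) / (b * cc)
  adj <- switch(adjustment,
                none = p,
                bonferroni = min(1, p * n_tests),
                bh = p) # BH applied jointly by the caller across sets
  data.frame(set_name = set_name, overlap = a,
             set_size = length(query_set), universe_size = length(universe),
             category_size = length(category_set),
             odds_ratio = or, p_value = p, adjusted_p = adj,
             adjustment = adjustment, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hallmark enrichment of a gene set
#'
#' Fisher enrichment of `query_set` in each of the 10 cancer hallmarks, the
#' hallmark memberships taken from the annotation's `hallmarks` list
#' column, Bonferroni-corrected across hallmarks by default.
#'
#' @param query_set genes of interest (e.g. genetically deregulated ERGs of
#'   one cancer type).
#' @param annotation compendium annotation with a `hallmarks` list column.
#' @param universe background universe (default: all annotated genes).
#' @param adjustment correction across hallmarks ("bonferroni", "bh",
#'   "none").
#' @return data.frame, one row per hallmark present in the annotation.
#' @export
hallmark_enrichment <- function(query_set, annotation,
                                universe = annotation$symbol,
                                adjustment = c("bonferroni", "bh", "none")) {
  adjustment <- match.arg(adjustment)
  labs <- sort(unique(unlist(annotation$hallmarks)))
  if (length(labs) == 0L) stop("annotation carries no hallmark labels", call. = FALSE)
  rows <- lapply(labs, function(h) {
    members <- annotation$symbol[vapply(annotation$hallmarks,
                                        function(x) h %in% x, logical(1))]
    set_enrichment_fisher(query_set, members, universe, set_name = h,
                          adjustment = "none")
  })
  res <- do.call(rbind, rows)
  res$adjustment <- adjustment
  res$adjusted_p <- switch(adjustment,
                           none = res$p_value,
                           bonferroni = pmin(1, res$p_value * length(labs)),
                           bh = p.adjust(res$p_value, method = "BH"))
  res
}

#' Read a ConsensusDriver-style score table
#' @param path TSV with columns gene, cancer, score.
#' @return data.frame(gene, cancer, score).
#' @export
read_consensus_driver <- function(path) {
  dt <- as.data.frame(fread(path, sep = "\t", header = TRUE))
  for (col in c("gene", "cancer", "score"))
    if (!col %in% names(dt))
      stop(sprintf("consensus driver table '%s' lacks column '%s'", path, col),
           call. = FALSE)
  dt$score <- as.numeric(dt$score)
  dt
}

#' Enrichment of a gene set among external consensus-predicted drivers
#'
#' Thresholds an external consensus score table (genes with score above
#' `score_cut` in any cancer count as predicted drivers) and tests
#' enrichment of `query_set` among them. The background universe is a
#' required argument because the result depends strongly on it.
#'
#' @param query_set genes of interest.
#' @param consensus_table [read_consensus_driver()] output.
#' @param universe background gene universe.
#' @param score_cut consensus score threshold (default 1.5).
#' @return One-row enrichment data.frame.
#' @export
consensus_driver_enrichment <- function(query_set, consensus_table, universe,
                                        score_cut = 1.5) {
  drivers <- unique(consensus_table$gene[consensus_table$score > score_cut])
  set_enrichment_fisher(query_set, drivers, universe,
                        set_name = "consensus_drivers")
}
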