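# Synthetic multi-cancer cohorts with planted signal. Every downstream stage
# is exercised against these; truth tables are the single source of planted
# effects and are only consumed by tests and the acceptance script.

# Named RNG substreams: each matrix draws from its own seed derived from the
# master seed and a label, so adding a matrix never perturbs existing ones.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 10007) %% 2147483647)
}

#' Generate a synthetic ERG compendium annotation
#'
#' Builds an annotation table with the structure of a curated epigenetic
#' regulator compendium: symbols, chromosomes 1-22 plus X, strand, TSS
#' coordinates, one of the 12 functional classes, random hallmark
#' memberships and tumor-suppressor/oncogene flags. Synthetic stand-in: no
#' real gene identities or coordinates.
#'
#' @param n_genes number of genes (426 matches the compendium scale).
#' @param seed RNG seed.
#' @return data.frame in the [read_compendium()] schema.
#' @export
make_synthetic_compendium <- function(n_genes = 426, seed = 1L) {
  set.seed(substream_seed(seed, "compendium"))
  symbols <- sprintf("ERG%04d", seq_len(n_genes))
  chroms <- c(as.character(1:22), "X")
  chromosome <- sample(chroms, n_genes, replace = TRUE,
                       prob = c(22:1, 8) / sum(c(22:1, 8)))
  tss <- integer(n_genes)
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    tss[idx] <- sort(sample.int(2e8, length(idx))) # ordered along chromosome
  }
  classes <- erg_classes()
  erg_class <- classes[1 + (seq_len(n_genes) - 1L) %% length(classes)]
  erg_class <- sample(erg_class) # all 12 classes represented, order random
  hm <- hallmark_labels()
  hallmarks <- lapply(seq_len(n_genes), function(i) {
    k <- rbinom(1, 3, 0.4)
    if (k == 0) character(0) else sort(sample(hm, k))
  })
  data.frame(symbol = symbols, chromosome = chromosome,
             strand = sample(c("+", "-"), n_genes, TRUE),
             tss = tss, erg_class = erg_class,
             hallmarks = I(hallmarks),
             tsg_flag = runif(n_genes) < 0.15,
             oncogene_flag = runif(n_genes) < 0.1,
             stringsAsFactors = FALSE)
}

#' Parameters for the synthetic cohort generator
#'
#' Defaults define the desk-scale study conditions: 6 cancer types, 300
#' genes, 200 tumor samples per cancer, 1% background mutation and deep-CNA
#' rates, CNA-to-expression coupling Z = a * CNA + eps with a = 0.8 and
#' eps ~ N(0, 0.5).
#'
#' @param n_cancers number of cancer types.
#' @param annotation gene annotation data.frame ([make_synthetic_compendium()]
#'   output); built from `n_genes` when NULL.
#' @param n_genes number of genes when `annotation` is NULL.
#' @param samples_per_cancer tumor samples per cancer type.
#' @param background_sna_rate per-gene per-sample Bernoulli mutation rate.
#' @param background_deep_cna_rate marginal per-gene deep CNA rate; deep
#'   events are laid out as contiguous blocks along each chromosome
#'   (geometric block length `cna_block_mean_len`) nested inside shallow
#'   blocks extended by `shallow_margin` genes on each side.
#' @param cna_block_mean_len mean deep-block length in genes.
#' @param shallow_margin genes of shallow (+/-1) call flanking each deep block.
#' @param cna_expr_slope,cna_expr_sd slope a and noise sd of Z = a*CNA + eps.
#' @param planted_drivers data.frame(gene, cancers, sna_rate, cna_rate,
#'   cna_direction) — `cancers` is "all" or a comma-separated cancer list;
#'   direction "amp" or "del".
#' @param planted_pairs data.frame(gene_a, gene_b, association
#'   ("cooccur"/"exclusive"), strength (target odds ratio), marginal).
#' @param eqtm_genes data.frame(gene, cpg_offset, sign (+1/-1), strength).
#' @param n_background_cpgs promoter CpGs with no planted coupling.
#' @param de_genes data.frame(gene, log2_effect) for tumor-vs-normal counts.
#' @param normals_per_cancer adjacent-normal samples per cancer (0 = none).
#' @param base_mean baseline negative-binomial mean read count.
#' @param nb_dispersion negative-binomial dispersion phi (var = mu + phi mu^2).
#' @param metastasis_labeled_frac fraction of samples given an M stage label.
#' @param metastasis_m1_frac fraction of labeled samples that are M1.
#' @param planted_metastasis data.frame(gene, m0_rate, m1_rate) of
#'   label-dependent mutation rates.
#' @param seed mandatory RNG seed; same seed and params give byte-identical
#'   output.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_cancers = 6,
                              annotation = NULL,
                              n_genes = 300,
                              samples_per_cancer = 200,
                              background_sna_rate = 0.01,
                              background_deep_cna_rate = 0.01,
                              cna_block_mean_len = 3,
                              shallow_margin = 2,
                              cna_expr_slope = 0.8,
                              cna_expr_sd = 0.5,
                              planted_drivers = NULL,
                              planted_pairs = NULL,
                              eqtm_genes = NULL,
                              n_background_cpgs = 30,
                              de_genes = NULL,
                              normals_per_cancer = 0,
                              base_mean = 200,
                              nb_dispersion = 0.1,
                              metastasis_labeled_frac = 0,
                              metastasis_m1_frac = 0.3,
                              planted_metastasis = NULL,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  rates <- c(background_sna_rate, background_deep_cna_rate,
             metastasis_labeled_frac, metastasis_m1_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]", call. = FALSE)
  if (cna_expr_sd <= 0) stop("cna_expr_sd must be > 0", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (is.null(annotation))
    annotation <- make_synthetic_compendium(n_genes, seed = seed)
  structure(list(
    n_cancers = n_cancers, annotation = annotation,
    samples_per_cancer = samples_per_cancer,
    background_sna_rate = background_sna_rate,
    background_deep_cna_rate = background_deep_cna_rate,
    cna_block_mean_len = cna_block_mean_len,
    shallow_margin = shallow_margin,
    cna_expr_slope = cna_expr_slope, cna_expr_sd = cna_expr_sd,
    planted_drivers = planted_drivers, planted_pairs = planted_pairs,
    eqtm_genes = eqtm_genes, n_background_cpgs = n_background_cpgs,
    de_genes = de_genes, normals_per_cancer = normals_per_cancer,
    base_mean = base_mean, nb_dispersion = nb_dispersion,
    metastasis_labeled_frac = metastasis_labeled_frac,
    metastasis_m1_frac = metastasis_m1_frac,
    planted_metastasis = planted_metastasis,
    seed = as.integer(seed)), class = "simulation_params")
}

# Contiguous CNA blocks for one chromosome: seeds placed per position
# (including virtual positions upstream of the first gene so marginal rates
# are position-independent), geometric block lengths, per-direction fields.
.sim_cna_chrom <- function(n_genes, n_samples, deep_rate, mean_len, margin) {
  if (deep_rate <= 0 || n_genes == 0)
    return(matrix(0L, n_genes, n_samples))
  p_len <- 1 / mean_len
  l_cap <- max(3L, as.integer(ceiling(log(0.001) / log(1 - p_len))))
  n_pos <- n_genes + l_cap
  seed_p <- deep_rate / mean_len / 2 # per direction
  cover_dir <- function() {
    seeds <- matrix(runif(n_pos * n_samples) < seed_p, n_pos, n_samples)
    lens <- matrix(pmin(1L + rgeom(n_pos * n_samples, p_len), l_cap),
                   n_pos, n_samples)
    deep <- matrix(FALSE, n_pos, n_samples)
    for (j in 0:(l_cap - 1L)) {
      act <- seeds & (lens > j)
      if (j == 0L) deep <- deep | act
      else {
        src <- seq_len(n_pos - j)
        deep[src + j, ] <- deep[src + j, ] | act[src, ]
      }
    }
    deep <- deep[(l_cap + 1L):n_pos, , drop = FALSE]
    shallow <- deep
    if (margin > 0L) {
      for (o in seq_len(min(margin, n_genes - 1L))) {
        up <- rbind(deep[-seq_len(o), , drop = FALSE],
                    matrix(FALSE, o, n_samples))
        dn <- rbind(matrix(FALSE, o, n_samples),
                    deep[seq_len(n_genes - o), , drop = FALSE])
        shallow <- shallow | up | dn
      }
    }
    list(deep = deep, shallow = shallow & !deep)
  }
  amp <- cover_dir(); del <- cover_dir()
  calls <- matrix(0L, n_genes, n_samples)
  calls[del$shallow] <- -1L; calls[del$deep] <- -2L
  calls[amp$shallow] <- 1L;  calls[amp$deep] <- 2L # amp wins rare conflicts
  calls
}

# Joint Bernoulli pair with given marginals and odds ratio (Plackett form).
.pair_cell_probs <- function(p1, p2, psi) {
  if (!is.finite(psi) || psi <= 0 || p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("infeasible pair strength for the given marginal rates", call. = FALSE)
  if (psi == 1) p11 <- p1 * p2
  else {
    s <- 1 + (p1 + p2) * (psi - 1)
    disc <- s^2 - 4 * psi * (psi - 1) * p1 * p2
    p11 <- (s - sqrt(disc)) / (2 * (psi - 1))
  }
  pr <- c(p11 = p11, p10 = p1 - p11, p01 = p2 - p11, p00 = 1 - p1 - p2 + p11)
  if (any(pr < -1e-12))
    stop("infeasible pair strength for the given marginal rates", call. = FALSE)
  pmax(pr, 0)
}

#' Simulate multi-cancer cohorts with planted drivers, pairs and eQTMs
#'
#' Generates one [cohort_omics()] per cancer type: Bernoulli background
#' mutations, contiguous-block CNAs, expression Z-scores coupled to CNA
#' (Z = a*CNA + eps), negative-binomial tumor (and optional normal) read
#' counts, promoter CpG methylation with planted expression coupling, and
#' optional metastasis labels. All planted effects are returned in truth
#' tables.
#'
#' @param params a [simulation_params()] object.
#' @return List with `cohorts` (named list of `cohort_omics`), `annotation`,
#'   and `truth` (list of data.frames: drivers, pairs, eqtm, de, metastasis).
#' @export
simulate_multi_cancer_cohorts <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  ann <- params$annotation
  genes <- sort(ann$symbol)
  ann <- ann[match(genes, ann$symbol), ]
  n <- params$samples_per_cancer
  cancer_codes <- sprintf("CT%02d", seq_len(params$n_cancers))
  seed <- params$seed

  pd <- params$planted_drivers
  if (!is.null(pd)) {
    stopifnot(all(pd$gene %in% genes))
    if (any(pd$sna_rate < 0 | pd$sna_rate > 1 | pd$cna_rate < 0 | pd$cna_rate > 1))
      stop("planted driver rates must lie in [0,1]", call. = FALSE)
  }
  pp <- params$planted_pairs
  if (!is.null(pp)) {
    if (is.null(pp$marginal)) pp$marginal <- 0.2
    for (i in seq_len(nrow(pp))) # fail fast on infeasible strengths
      .pair_cell_probs(pp$marginal[i], pp$marginal[i], pp$strength[i])
  }

  # chromosome layout for CNA blocks: annotation order along each chromosome
  chrom_order <- order(ann$chromosome, ann$tss)
  chrom_of <- ann$chromosome[chrom_order]

  cohorts <- list()
  for (ct in cancer_codes) {
    samples <- sprintf("%s_S%03d", ct, seq_len(n))

    set.seed(substream_seed(seed, paste0("sna:", ct)))
    sna <- matrix(rbinom(length(genes) * n, 1L, params$background_sna_rate),
                  length(genes), n, dimnames = list(genes, samples))

    set.seed(substream_seed(seed, paste0("cna:", ct)))
    cna <- matrix(0L, length(genes), n, dimnames = list(genes, samples))
    for (ch in unique(chrom_of)) {
      idx <- chrom_order[chrom_of == ch]
      cna[idx, ] <- .sim_cna_chrom(length(idx), n,
                                   params$background_deep_cna_rate,
                                   params$cna_block_mean_len,
                                   params$shallow_margin)
    }

    set.seed(substream_seed(seed, paste0("drivers:", ct)))
    if (!is.null(pd)) {
      for (i in seq_len(nrow(pd))) {
        affected <- identical(pd$cancers[i], "all") ||
          ct %in% strsplit(pd$cancers[i], ",")[[1]]
        if (!affected) next
        g <- pd$gene[i]
        sna[g, ] <- rbinom(n, 1L, pd$sna_rate[i])
        deep <- if (identical(pd$cna_direction[i], "del")) -2L else 2L
        hit <- runif(n) < pd$cna_rate[i]
        cna[g, hit] <- deep
      }
    }

    set.seed(substream_seed(seed, paste0("pairs:", ct)))
    if (!is.null(pp)) {
      for (i in seq_len(nrow(pp))) {
        pr <- .pair_cell_probs(pp$marginal[i], pp$marginal[i], pp$strength[i])
        cell <- sample.int(4L, n, replace = TRUE, prob = pr)
        sna[pp$gene_a[i], ] <- as.integer(cell %in% c(1L, 2L))
        sna[pp$gene_b[i], ] <- as.integer(cell %in% c(1L, 3L))
      }
    }

    set.seed(substream_seed(seed, paste0("metastasis:", ct)))
    metastasis <- NULL
    if (params$metastasis_labeled_frac > 0) {
      labeled <- runif(n) < params$metastasis_labeled_frac
      m1 <- runif(n) < params$metastasis_m1_frac
      metastasis <- ifelse(labeled, ifelse(m1, "M1", "M0"), NA_character_)
      pm <- params$planted_metastasis
      if (!is.null(pm)) {
        for (i in seq_len(nrow(pm))) {
          rate <- ifelse(!is.na(metastasis) & metastasis == "M1",
                         pm$m1_rate[i], pm$m0_rate[i])
          sna[pm$gene[i], ] <- rbinom(n, 1L, rate)
        }
      }
    }

    set.seed(substream_seed(seed, paste0("z:", ct)))
    expr_z <- params$cna_expr_slope * cna +
      matrix(rnorm(length(genes) * n, 0, params$cna_expr_sd), length(genes), n)
    dimnames(expr_z) <- list(genes, samples)

    set.seed(substream_seed(seed, paste0("counts:", ct)))
    mu <- exp(rnorm(length(genes), log(params$base_mean), 0.6))
    names(mu) <- genes
    tumor_mu <- mu
    if (!is.null(params$de_genes)) {
      dg <- params$de_genes
      tumor_mu[dg$gene] <- mu[dg$gene] * 2^dg$log2_effect
    }
    sf <- exp(rnorm(n, 0, 0.2))
    tumor_counts <- matrix(rnbinom(length(genes) * n,
                                   mu = outer(tumor_mu, sf),
                                   size = 1 / params$nb_dispersion),
                           length(genes), n, dimnames = list(genes, samples))
    normal_counts <- NULL
    if (params$normals_per_cancer > 0) {
      m <- params$normals_per_cancer
      sfn <- exp(rnorm(m, 0, 0.2))
      normal_counts <- matrix(rnbinom(length(genes) * m,
                                      mu = outer(mu, sfn),
                                      size = 1 / params$nb_dispersion),
                              length(genes), m,
                              dimnames = list(genes,
                                              sprintf("%s_N%03d", ct, seq_len(m))))
    }

    set.seed(substream_seed(seed, paste0("meth:", ct)))
    methylation <- NULL
    eq <- params$eqtm_genes
    n_bg <- params$n_background_cpgs
    if (!is.null(eq) || n_bg > 0) {
      ids <- character(0); chrom <- character(0); pos <- integer(0)
      rows <- list()
      if (!is.null(eq)) {
        for (i in seq_len(nrow(eq))) {
          g <- eq$gene[i]
          a <- ann[ann$symbol == g, ]
          off <- eq$cpg_offset[i]
          p <- if (a$strand == "+") a$tss + off else a$tss - off
          ids <- c(ids, sprintf("cpg_planted_%s", g))
          chrom <- c(chrom, a$chromosome); pos <- c(pos, as.integer(p))
          e <- log2(tumor_counts[g, ] + 1)
          zex <- if (sd(e) > 0) (e - mean(e)) / sd(e) else e * 0
          lg <- eq$sign[i] * eq$strength[i] * zex + rnorm(n, 0, 0.5)
          rows[[length(rows) + 1L]] <- 1 / (1 + exp(-lg))
        }
      }
      if (n_bg > 0) {
        bg_genes <- sample(genes, n_bg, replace = TRUE)
        for (k in seq_len(n_bg)) {
          a <- ann[ann$symbol == bg_genes[k], ]
          off <- sample(-1000:500, 1)
          p <- if (a$strand == "+") a$tss + off else a$tss - off
          ids <- c(ids, sprintf("cpg_bg_%04d", k))
          chrom <- c(chrom, a$chromosome); pos <- c(pos, as.integer(p))
          rows[[length(rows) + 1L]] <- stats::rbeta(n, 2, 2)
        }
      }
      betas <- do.call(rbind, rows)
      dimnames(betas) <- list(ids, samples)
      methylation <- list(betas = betas,
                          map = data.frame(cpg_id = ids, chrom = chrom,
                                           pos = pos, stringsAsFactors = FALSE))
    }

    cohorts[[ct]] <- cohort_omics(ct, sna = sna, cna = cna, expr_z = expr_z,
                                  tumor_counts = tumor_counts,
                                  normal_counts = normal_counts,
                                  methylation = methylation,
                                  metastasis = metastasis)
  }

  truth <- list(
    drivers = if (is.null(pd)) NULL else as.data.frame(pd),
    pairs = if (is.null(pp)) NULL else as.data.frame(pp),
    eqtm = if (is.null(params$eqtm_genes)) NULL else {
      eq <- as.data.frame(params$eqtm_genes)
      eq$cpg_id <- sprintf("cpg_planted_%s", eq$gene)
      eq
    },
    de = if (is.null(params$de_genes)) NULL else as.data.frame(params$de_genes),
    metastasis = if (is.null(params$planted_metastasis)) NULL else
      as.data.frame(params$planted_metastasis))
  list(cohorts = cohorts, annotation = ann, truth = truth)
}

#' Simulate paired tumor/normal negative-binomial count matrices
#'
#' Counts follow NB(mu_g * s_j, phi) with per-sample library-size factors
#' s_j; genes listed in `de_genes` have tumor mean mu_g * 2^log2_effect.
#'
#' @param genes character vector of gene names (or an integer count).
#' @param n_tumor,n_normal sample sizes.
#' @param de_genes data.frame(gene, log2_effect) or NULL.
#' @param base_mean baseline NB mean.
#' @param dispersion NB dispersion phi > 0 (var = mu + phi mu^2).
#' @param tumor_lib_factors,normal_lib_factors optional fixed library size
#'   factors (default lognormal).
#' @param seed RNG seed.
#' @return List with `tumor`, `normal` count matrices and `truth`.
#' @export
simulate_tumor_normal_counts <- function(genes, n_tumor, n_normal,
                                         de_genes = NULL, base_mean = 200,
                                         dispersion = 0.1,
                                         tumor_lib_factors = NULL,
                                         normal_lib_factors = NULL,
                                         seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("G%04d", seq_len(genes))
  if (!is.null(de_genes) && any(!is.finite(de_genes$log2_effect)))
    stop("de_genes effects must be finite", call. = FALSE)
  set.seed(substream_seed(seed, "tumor_normal"))
  mu <- exp(rnorm(length(genes), log(base_mean), 0.6))
  names(mu) <- genes
  tumor_mu <- mu
  if (!is.null(de_genes)) tumor_mu[de_genes$gene] <- mu[de_genes$gene] * 2^de_genes$log2_effect
  sft <- if (is.null(tumor_lib_factors)) exp(rnorm(n_tumor, 0, 0.2)) else tumor_lib_factors
  sfn <- if (is.null(normal_lib_factors)) exp(rnorm(n_normal, 0, 0.2)) else normal_lib_factors
  tumor <- matrix(rnbinom(length(genes) * n_tumor, mu = outer(tumor_mu, sft),
                          size = 1 / dispersion),
                  length(genes), n_tumor,
                  dimnames = list(genes, sprintf("T%03d", seq_len(n_tumor))))
  normal <- matrix(rnbinom(length(genes) * n_normal, mu = outer(mu, sfn),
                           size = 1 / dispersion),
                   length(genes), n_normal,
                   dimnames = list(genes, sprintf("N%03d", seq_len(n_normal))))
  list(tumor = tumor, normal = normal,
       truth = list(base_mu = mu, de_genes = de_genes,
                    tumor_lib_factors = sft, normal_lib_factors = sfn))
}
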