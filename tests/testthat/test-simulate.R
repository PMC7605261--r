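test_that("zero rates give empty alteration matrices and pure-noise Z", {
  p <- simulation_params(n_cancers = 2, n_genes = 30, samples_per_cancer = 40,
                         background_sna_rate = 0, background_deep_cna_rate = 0,
                         seed = 1)
  sim <- simulate_multi_cancer_cohorts(p)
  for (co in sim$cohorts) {
    expect_true(all(co$sna == 0))
    expect_true(all(co$cna == 0))
    expect_gt(sd(co$expr_z), 0) # Z reduces to the noise term
    expect_lt(abs(mean(co$expr_z)), 0.1)
  }
})

test_that("near-noiseless CNA-expression coupling gives r near 1", {
  p <- simulation_params(n_cancers = 1, n_genes = 40, samples_per_cancer = 150,
                         background_deep_cna_rate = 0.2,
                         cna_expr_slope = 1, cna_expr_sd = 1e-6, seed = 2)
  co <- simulate_multi_cancer_cohorts(p)$cohorts[[1]]
  varying <- which(apply(co$cna, 1, sd) > 0)
  expect_gt(length(varying), 5)
  rs <- vapply(varying, function(i) cor(co$cna[i, ], co$expr_z[i, ]), 0)
  expect_true(all(rs > 0.999))
})

test_that("identical seed and params reproduce the cohorts exactly", {
  mk <- function() simulate_multi_cancer_cohorts(
    simulation_params(n_cancers = 2, n_genes = 25, samples_per_cancer = 30,
                      eqtm_genes = data.frame(gene = "ERG0003",
                                              cpg_offset = -100,
                                              sign = -1, strength = 2),
                      metastasis_labeled_frac = 0.5, seed = 99))
  a <- mk(); b <- mk()
  expect_identical(a$cohorts$CT01$sna, b$cohorts$CT01$sna)
  expect_identical(a$cohorts$CT02$cna, b$cohorts$CT02$cna)
  expect_identical(a$cohorts$CT01$expr_z, b$cohorts$CT01$expr_z)
  expect_identical(a$cohorts$CT01$methylation$betas,
                   b$cohorts$CT01$methylation$betas)
  expect_identical(a$cohorts$CT01$metastasis, b$cohorts$CT01$metastasis)
})

test_that("marginal alteration frequencies converge to the nominal rates", {
  p <- simulation_params(n_cancers = 1, n_genes = 60, samples_per_cancer = 2000,
                         background_sna_rate = 0.03,
                         background_deep_cna_rate = 0.05, seed = 4)
  co <- simulate_multi_cancer_cohorts(p)$cohorts[[1]]
  n <- 2000
  se_sna <- sqrt(0.03 * 0.97 / n)
  sna_f <- rowMeans(co$sna > 0)
  expect_true(mean(abs(sna_f - 0.03) <= 3 * se_sna) > 0.95)
  se_cna <- sqrt(0.05 * 0.95 / n)
  deep_f <- rowMeans(abs(co$cna) == 2)
  # block structure correlates neighbours but each gene's marginal is Bernoulli
  expect_true(mean(abs(deep_f - 0.05) <= 3 * se_cna) > 0.9)
  expect_lt(abs(mean(deep_f) - 0.05), 3 * se_cna)
})

test_that("deep CNA events sit inside shallow blocks of the same sign", {
  p <- simulation_params(n_cancers = 1, n_genes = 80, samples_per_cancer = 50,
                         background_deep_cna_rate = 0.1, seed = 6)
  co <- simulate_multi_cancer_cohorts(p)$cohorts[[1]]
  expect_true(any(co$cna == 1) && any(co$cna == 2))
  # shallow calls appear only adjacent (along the gene axis) to deep calls
  ann <- simulate_multi_cancer_cohorts(p)$annotation
  ord <- order(ann$chromosome, ann$tss)
  m <- co$cna[ann$symbol[ord], ]
  shallow <- which(abs(m) == 1, arr.ind = TRUE)
  near_deep <- vapply(seq_len(nrow(shallow)), function(k) {
    i <- shallow[k, 1]; j <- shallow[k, 2]
    any(abs(m[max(1, i - 2):min(nrow(m), i + 2), j]) == 2)
  }, logical(1))
  expect_true(mean(near_deep) > 0.95)
})

test_that("planted co-occurring pairs realize the requested odds ratio", {
  ors <- vapply(1:20, function(s) {
    p <- simulation_params(n_cancers = 1, n_genes = 20, samples_per_cancer = 500,
                           background_sna_rate = 0, background_deep_cna_rate = 0,
                           planted_pairs = data.frame(gene_a = "ERG0001",
                                                      gene_b = "ERG0002",
                                                      association = "cooccur",
                                                      strength = 8,
                                                      marginal = 0.2),
                           seed = 100 + s)
    co <- simulate_multi_cancer_cohorts(p)$cohorts[[1]]
    a <- co$sna["ERG0001", ] > 0; b <- co$sna["ERG0002", ] > 0
    st <- pair_table_stats(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
    st$odds_ratio
  }, 0)
  expect_true(all(ors > 4 & ors < 16)) # within 2-fold of 8
})

test_that("infeasible pair strength is rejected up front", {
  p <- simulation_params(n_cancers = 1, n_genes = 10, samples_per_cancer = 50,
                         seed = 1)
  expect_error(simulation_params(n_cancers = 1, n_genes = 10,
                                 samples_per_cancer = 50,
                                 planted_pairs = data.frame(
                                   gene_a = "ERG0001", gene_b = "ERG0002",
                                   association = "exclusive", strength = 0,
                                   marginal = 0.9),
                                 seed = 1) |>
                 simulate_multi_cancer_cohorts(),
               "infeasible pair strength")
})

test_that("tumor/normal counts carry the planted fold changes", {
  # no effect: per-gene tumor/normal mean ratios near 1
  s0 <- simulate_tumor_normal_counts(50, 20, 20, seed = 10,
                                     tumor_lib_factors = rep(1, 20),
                                     normal_lib_factors = rep(1, 20))
  lr <- log2(rowMeans(s0$tumor) + 0.5) - log2(rowMeans(s0$normal) + 0.5)
  expect_lt(max(abs(lr)), 0.7)

  # planted +3 log2 effect recovered within +/- 0.5
  de <- data.frame(gene = "G0001", log2_effect = 3)
  s1 <- simulate_tumor_normal_counts(50, 20, 20, de_genes = de,
                                     base_mean = 200, seed = 11,
                                     tumor_lib_factors = rep(1, 20),
                                     normal_lib_factors = rep(1, 20))
  lr1 <- log2(mean(s1$tumor["G0001", ])) - log2(mean(s1$normal["G0001", ]))
  expect_lt(abs(lr1 - 3), 0.5)
})

test_that("a doubled library factor is recovered by median-of-ratios", {
  s <- simulate_tumor_normal_counts(200, 10, 10, seed = 12,
                                    tumor_lib_factors = c(2, rep(1, 9)),
                                    normal_lib_factors = rep(1, 10))
  sf <- size_factors(cbind(s$tumor, s$normal))
  # independent median-of-ratios oracle
  all_c <- cbind(s$tumor, s$normal)
  ref <- exp(rowMeans(log(all_c)))
  ok <- is.finite(ref) & ref > 0
  oracle <- apply(all_c[ok, ], 2, function(x) median(x / ref[ok]))
  expect_equal(unname(sf), unname(oracle))
  expect_lt(abs(sf[1] / median(sf[-1]) - 2), 0.3)
})

test_that("screen simulation plants fold effects and is self-consistent", {
  lib <- make_guide_library(paste0("GENE", 1:40), seed = 20)
  # null screen: day-14/day-0 log ratios center on zero
  s0 <- simulate_screen_data(lib, depth = 5e4, seed = 21)
  lr <- log2((s0$counts[, "D14"] + 0.5) / (s0$counts[, "D0"] + 0.5))
  expect_lt(abs(median(lr)), 0.15)

  # a 16-fold enriched guide shows within 2-fold of 16
  planted <- data.frame(guide_id = lib$guide_id[1], fold = 16)
  s1 <- simulate_screen_data(lib, depth = 1e5, planted = planted, seed = 22)
  obs <- (s1$counts[1, "D14"] / sum(s1$counts[, "D14"])) /
    (s1$counts[1, "D0"] / sum(s1$counts[, "D0"]))
  expect_gt(obs, 8); expect_lt(obs, 32)
  expect_equal(s1$truth$direction, "enriched")
})

test_that("duplicate spacers cannot enter a generated library", {
  lib <- make_guide_library(paste0("GENE", 1:100), seed = 23)
  expect_false(anyDuplicated(lib$spacer) > 0)
  gpg <- table(lib$gene)
  expect_true(all(gpg >= 1 & gpg <= 4))
})
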