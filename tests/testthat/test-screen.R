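test_that("FASTQ counting assigns unique matches and conserves reads", {
  lib <- data.frame(guide_id = c("g1", "g2"), gene = c("A", "B"),
                    spacer = c(strrep("AC", 10), strrep("GT", 10)))
  flank <- "TTTTTTTTTT"
  reads <- c(paste0(flank, lib$spacer[1], flank),
             paste0(flank, lib$spacer[1], flank),
             paste0(flank, lib$spacer[1], flank),
             paste0(flank, lib$spacer[2], flank),
             paste0(flank, strrep("CA", 10), flank)) # matches nothing
  f <- write_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  out <- count_guides_from_fastq(c(cond = f), lib)
  expect_equal(out$counts[, "cond"], c(g1 = 3L, g2 = 1L))
  expect_equal(out$stats$mapped / out$stats$total, 0.8)
  expect_equal(out$stats$mapped + out$stats$ambiguous + out$stats$unmapped,
               out$stats$total)

  # a read containing both spacers is ambiguous and counted in neither
  reads2 <- c(paste0(lib$spacer[1], lib$spacer[2]))
  f2 <- write_fastq(reads2, withr::local_tempfile(fileext = ".fastq"))
  out2 <- count_guides_from_fastq(c(x = f2), lib)
  expect_equal(sum(out2$counts), 0L)
  expect_equal(out2$stats$ambiguous, 1L)

  # malformed FASTQ raises a parse error
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(count_guides_from_fastq(c(x = bad), lib), "malformed FASTQ")
})

test_that("counting is order-independent and mismatch mode works", {
  set.seed(71)
  lib <- data.frame(guide_id = c("g1", "g2"), gene = c("A", "B"),
                    spacer = random_spacer(2))
  reads <- c(rep(paste0("AAAA", lib$spacer[1], "CCCC"), 4),
             rep(paste0("AAAA", lib$spacer[2], "CCCC"), 2))
  f1 <- write_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  f2 <- write_fastq(rev(reads), withr::local_tempfile(fileext = ".fastq"))
  c1 <- count_guides_from_fastq(c(a = f1), lib)$counts
  c2 <- count_guides_from_fastq(c(a = f2), lib)$counts
  expect_equal(c1, c2)

  # one mismatched base: missed at 0 mismatches, found at 1
  mut <- lib$spacer[1]
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(mut, 10, 10))[1]
  fm <- write_fastq(paste0("AAAA", mut, "CCCC"),
                    withr::local_tempfile(fileext = ".fastq"))
  expect_equal(sum(count_guides_from_fastq(c(m = fm), lib)$counts), 0L)
  expect_equal(count_guides_from_fastq(c(m = fm), lib,
                                       max_mismatch = 1)$counts["g1", "m"], 1L)
})

test_that("generated FASTQ recounts to the generator's count table", {
  lib <- make_guide_library(paste0("GENE", 1:15), seed = 72)
  dir <- withr::local_tempdir()
  sim <- simulate_screen_data(lib, timepoints = c("D0", "D14"), depth = 3000,
                              fastq_dir = dir, seed = 73)
  out <- count_guides_from_fastq(sim$fastq_paths, lib)
  expect_identical(out$counts, sim$counts)
  expect_true(all(out$stats$unmapped == 0L))
})

test_that("library representation statistics match their definitions", {
  uni <- matrix(5L, 10, 1, dimnames = list(paste0("g", 1:10), "D0"))
  qc <- library_representation(uni)
  expect_equal(qc$skew_ratio_90_10, 1)
  expect_equal(qc$gini, 0)
  expect_equal(qc$zero_frac, 0)

  # one guide holding all reads: Gini = 1 - 1/k
  k <- 8
  mono <- matrix(c(rep(0L, k - 1), 400L), k, 1,
                 dimnames = list(paste0("g", 1:k), "D0"))
  expect_equal(library_representation(mono)$gini, 1 - 1 / k)

  # Dirichlet-multinomial fixture vs the definitional brute force
  set.seed(74)
  p <- rgamma(30, 2); p <- p / sum(p)
  x <- as.integer(rmultinom(1, 5000, p))
  m <- matrix(x, 30, 1, dimnames = list(paste0("g", 1:30), "D0"))
  expect_equal(library_representation(m)$gini, gini_brute(x))
  expect_error(library_representation(matrix(0L, 0, 0)), "empty")
})

test_that("the guide test is null-calm and flags planted effects", {
  lib <- make_guide_library(paste0("GENE", 1:50), seed = 75)
  cnt <- matrix(100L, nrow(lib), 2,
                dimnames = list(lib$guide_id, c("D0", "D14")))
  r0 <- test_guides(cnt, list(late = "D14", early = "D0"), lib)
  expect_true(all(r0$z == 0))
  expect_true(all(r0$p_value == 1))
  expect_error(test_guides(cnt, list(late = "D99", early = "D0")), "D99")

  sim <- simulate_screen_data(lib, timepoints = c("D0", "D14"), depth = 1e5,
                              planted = data.frame(guide_id = lib$guide_id[1],
                                                   fold = 16),
                              seed = 76)
  r <- test_guides(sim$counts, list(late = "D14", early = "D0"), lib)
  expect_lt(r$p_value[r$guide_id == lib$guide_id[1]], 0.001)
  expect_equal(r$direction[r$guide_id == lib$guide_id[1]], "enriched")
})

test_that("consensus hit-calling enforces dual thresholds and timepoints", {
  mk <- function(method, comparison, guide, gene, p, dir)
    data.frame(method = method, comparison = comparison, guide_id = guide,
               gene = gene, p_value = p, direction = dir)
  tps <- c("D14", "D21", "D28")
  calls <- rbind(
    # gene GA: one guide passing both methods at all timepoints, enriched
    do.call(rbind, lapply(tps, function(tp) rbind(
      mk("methodA", tp, "GA_g1", "GA", 1e-5, "enriched"),
      mk("methodB", tp, "GA_g1", "GA", 1e-3, "enriched")))),
    # gene GB: passes methodA (1e-4 < 0.001) but fails methodB (0.05 > 0.01)
    do.call(rbind, lapply(tps, function(tp) rbind(
      mk("methodA", tp, "GB_g1", "GB", 1e-4, "enriched"),
      mk("methodB", tp, "GB_g1", "GB", 0.05, "enriched")))),
    # gene GC: consensus at D14/D21 only
    do.call(rbind, lapply(tps, function(tp) rbind(
      mk("methodA", tp, "GC_g1", "GC", ifelse(tp == "D28", 0.9, 1e-5), "depleted"),
      mk("methodB", tp, "GC_g1", "GC", ifelse(tp == "D28", 0.9, 1e-3), "depleted")))),
    # gene GD: direction flips between timepoints
    do.call(rbind, lapply(tps, function(tp) rbind(
      mk("methodA", tp, "GD_g1", "GD", 1e-5,
         ifelse(tp == "D28", "depleted", "enriched")),
      mk("methodB", tp, "GD_g1", "GD", 1e-3,
         ifelse(tp == "D28", "depleted", "enriched"))))),
    # gene GE: methods disagree on direction
    do.call(rbind, lapply(tps, function(tp) rbind(
      mk("methodA", tp, "GE_g1", "GE", 1e-5, "enriched"),
      mk("methodB", tp, "GE_g1", "GE", 1e-3, "depleted")))))
  out <- consensus_hits(calls, required_comparisons = tps)
  expect_equal(out$candidates, "GA")
  gc_row <- out$gene_calls[out$gene_calls$gene == "GC", ]
  expect_equal(gc_row$n_comparisons, 2L)
  expect_false(gc_row$candidate)
  gd_row <- out$gene_calls[out$gene_calls$gene == "GD", ]
  expect_equal(gd_row$direction, "mixed")
  expect_false("GE" %in% out$gene_calls$gene) # never a consensus guide
  expect_equal(out$venn_counts$n_guides[out$venn_counts$pattern ==
                                          "D14&D21&D28"], 2L) # GA, GD
  expect_equal(out$venn_counts$n_guides[out$venn_counts$pattern ==
                                          "D14&D21"], 1L) # GC

  # monotonicity: tightening a threshold never adds a hit
  tighter <- consensus_hits(calls, required_comparisons = tps,
                            method_thresholds = c(methodA = 1e-6,
                                                  methodB = 0.01))
  expect_true(all(tighter$candidates %in% out$candidates))
  expect_error(consensus_hits(rbind(mk("methodA", "D14", "g1", "A", 1e-5, "enriched"),
                                    mk("methodB", "D14", "g2", "A", 1e-5, "enriched"))),
               "no overlapping guides")
})

test_that("metastasis comparison averages per-cancer subset frequencies", {
  sna <- matrix(0L, 2, 30)
  sna[1, c(1, 2, 11)] <- 1L # mutated in 2/10 M1 and 1/20 M0
  co <- tiny_cohort(sna, matrix(0L, 2, 30),
                    metastasis = c(rep("M1", 10), rep("M0", 20)))
  r <- metastasis_mutation_comparison(list(C1 = co), c("G01", "G02"))
  expect_equal(r$mean_pct_M1[r$gene == "G01"], 20)
  expect_equal(r$mean_pct_M0[r$gene == "G01"], 5)
  expect_equal(r$mean_pct_M1[r$gene == "G02"], 0)

  # a cancer lacking M1 samples contributes nothing
  co_no_m1 <- tiny_cohort(matrix(1L, 2, 10), matrix(0L, 2, 10),
                          metastasis = rep("M0", 10))
  r2 <- metastasis_mutation_comparison(list(C1 = co, C2 = co_no_m1), "G01")
  expect_equal(r2$n_cancers, 1L)
  expect_equal(r2$mean_pct_M1, 20)
  expect_warning(metastasis_mutation_comparison(list(C1 = co), "NOPE"),
                 "absent")
})

test_that("planted metastasis-enriched genes show higher M1 frequencies", {
  hits <- vapply(1:20, function(s) {
    p <- simulation_params(n_cancers = 2, n_genes = 20, samples_per_cancer = 100,
                           metastasis_labeled_frac = 0.6,
                           planted_metastasis = data.frame(gene = "ERG0001",
                                                           m0_rate = 0.05,
                                                           m1_rate = 0.3),
                           seed = 700 + s)
    sim <- simulate_multi_cancer_cohorts(p)
    r <- metastasis_mutation_comparison(sim$cohorts, "ERG0001")
    r$mean_pct_M1 > r$mean_pct_M0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
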