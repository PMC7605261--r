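test_that("competition ranking applies the shared-score and gap rules", {
  r <- competition_rank(c("C", "A", "B", "D"),
                        c(2, 5, 5, 7), c(4, 12, 12, 3))
  expect_equal(setNames(r$ranking_score, r$gene),
               c(C = 1L, A = 2L, B = 2L, D = 4L))
  # total tie: everyone scores 1
  r2 <- competition_rank(paste0("g", 1:4), rep(3, 4), rep(1.5, 4))
  expect_true(all(r2$ranking_score == 1L))
  # a subsequent distinct gene picks up the y + x gap
  r3 <- competition_rank(paste0("g", 1:5), c(3, 3, 3, 3, 4), c(1, 1, 1, 1, 0))
  expect_equal(r3$ranking_score, c(1L, 1L, 1L, 1L, 5L))
  expect_equal(competition_rank("only", 2, 0.5)$ranking_score, 1L)
  # unqualified genes carry no score
  r4 <- competition_rank(c("a", "b"), c(0, 3), c(0, 1))
  expect_true(is.na(r4$ranking_score[1]))
  expect_error(competition_rank("a", 1, NaN), "NaN")
})

test_that("competition ranking equals the brute-force strictly-lower rule", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    primary <- sample(0:6, n, TRUE)
    secondary <- round(runif(n), sample(0:2, 1)) # forced ties
    r <- competition_rank(paste0("g", seq_len(n)), primary, secondary)
    expect_identical(r$ranking_score,
                     brute_competition_rank(primary, secondary))
  }
})

test_that("pan-cancer driver scoring ranks a strong multi-cancer gene first", {
  set.seed(52)
  mk <- function(strong_frac) {
    lapply(setNames(nm = c("CA", "CB", "CC")), function(ct) {
      sna <- matrix(rbinom(20 * 100, 1, 0.01), 20, 100)
      sna[1, ] <- rbinom(100, 1, strong_frac) # gene G01
      cna <- matrix(0L, 20, 100)
      cna[1, seq_len(round(100 * strong_frac))] <- 2L
      z <- matrix(rnorm(2000, 0, 0.5), 20, 100)
      tiny_cohort(sna, cna, expr_z = z, cancer_code = ct)
    })
  }
  ds <- pan_cancer_driver_score(mk(0.2))
  expect_equal(ds$gene[which(ds$pan_cancer_score == 1)], "G01")
  expect_equal(ds$cna_direction[ds$gene == "G01"], "amp")
  expect_equal(ds$combined[ds$gene == "G01"],
               1 * ds$sna_rank[ds$gene == "G01"] +
                 1 * ds$cna_rank[ds$gene == "G01"] +
                 0.5 * ifelse(is.na(ds$z_rank[ds$gene == "G01"]), 0,
                              ds$z_rank[ds$gene == "G01"]))
})

test_that("the 5% per-cancer filter gates driver-track qualification", {
  sna <- matrix(0L, 2, 200)
  sna[1, 1:9] <- 1L  # 4.5% < 5%: unqualified
  sna[2, 1:10] <- 1L # exactly 5%: qualified
  co <- tiny_cohort(sna, matrix(0L, 2, 200),
                    expr_z = matrix(0, 2, 200))
  ds <- suppressWarnings(pan_cancer_driver_score(list(T1 = co)))
  expect_true(is.na(ds$sna_rank[ds$gene == "G01"]))
  expect_true(is.na(ds$pan_cancer_score[ds$gene == "G01"]))
  expect_equal(ds$sna_primary[ds$gene == "G02"], 1)
  expect_equal(ds$pan_cancer_score[ds$gene == "G02"], 1L)
})

test_that("identical track profiles share one pan-cancer position", {
  sna <- matrix(0L, 3, 100)
  sna[1, 1:20] <- 1L; sna[2, 1:20] <- 1L # identical genes
  co <- tiny_cohort(sna, matrix(0L, 3, 100), expr_z = matrix(0, 3, 100))
  ds <- pan_cancer_driver_score(list(T1 = co))
  expect_equal(ds$pan_cancer_score[ds$gene == "G01"],
               ds$pan_cancer_score[ds$gene == "G02"])
})

test_that("raising a gene's alteration frequency never worsens its position", {
  set.seed(53)
  base_sna <- matrix(rbinom(15 * 100, 1, 0.05), 15, 100)
  cna <- matrix(sample(c(-2L, 0L, 2L), 1500, TRUE, c(.05, .9, .05)), 15, 100)
  z <- matrix(rnorm(1500), 15, 100)
  pos_of <- function(sna) {
    ds <- pan_cancer_driver_score(list(T1 = tiny_cohort(sna, cna, expr_z = z)))
    ds$pan_cancer_score[ds$gene == "G05"]
  }
  p_before <- pos_of(base_sna)
  boosted <- base_sna
  boosted[5, ] <- pmax(boosted[5, ], rbinom(100, 1, 0.3))
  p_after <- pos_of(boosted)
  if (is.na(p_before)) expect_true(TRUE) else expect_lte(p_after, p_before)
})

test_that("driver scores are invariant to gene input order", {
  set.seed(54)
  sna <- matrix(rbinom(10 * 80, 1, 0.1), 10, 80)
  cna <- matrix(sample(c(-2L, 0L, 2L), 800, TRUE, c(.08, .84, .08)), 10, 80)
  z <- matrix(rnorm(800), 10, 80)
  co <- tiny_cohort(sna, cna, expr_z = z)
  perm <- sample(10)
  co2 <- cohort_omics("TST", sna = co$sna[perm, ], cna = co$cna[perm, ],
                      expr_z = co$expr_z[perm, ])
  d1 <- pan_cancer_driver_score(list(T = co))
  d2 <- pan_cancer_driver_score(list(T = co2))
  expect_equal(d1[order(d1$gene), ], d2[order(d2$gene), ],
               ignore_attr = TRUE)
})

test_that("multi-omics driver score is the mean of within-cancer percentiles", {
  sna <- matrix(0L, 4, 100); cna <- matrix(0L, 4, 100); z <- matrix(0, 4, 100)
  sna[1, 1:50] <- 1L; cna[1, 1:40] <- 2L; z[1, 1:30] <- 5
  sna[2, 1:10] <- 1L; cna[2, 1:5] <- -2L; z[2, 1:3] <- -5
  co <- tiny_cohort(sna, cna, expr_z = z)
  mo <- multi_omics_driver_score(co)
  expect_equal(mo$score[1], 1.0) # within-cancer maximum on all tracks
  expect_lt(mo$score[4], mo$score[2])

  # brute-force percentile oracle on a random fixture
  set.seed(55)
  sna <- matrix(rbinom(20 * 60, 1, 0.2), 20, 60)
  cna <- matrix(sample(c(-2L, 0L, 2L), 1200, TRUE, c(.15, .7, .15)), 20, 60)
  z <- matrix(rnorm(1200, 0, 2), 20, 60)
  co2 <- tiny_cohort(sna, cna, expr_z = z)
  mo2 <- multi_omics_driver_score(co2)
  pct <- function(x) rank(x, ties.method = "average") / length(x)
  oracle <- (pct(rowMeans(sna > 0)) +
               pct(pmax(rowMeans(cna == 2), rowMeans(cna == -2))) +
               pct(rowMeans(abs(z) > 2))) / 3
  expect_equal(mo2$score, unname(oracle))
  expect_error(multi_omics_driver_score(
    tiny_cohort(matrix(0L, 1, 5), matrix(0L, 1, 5), expr_z = matrix(0, 1, 5))),
    "at least 2 genes")
})

test_that("Fisher set enrichment agrees with the hypergeometric law", {
  # expectation-level overlap: OR near 1, p large
  univ <- paste0("u", 1:200)
  q <- univ[1:20]; cat_set <- univ[c(1:3, 101:127)] # overlap 3 = 20*30/200
  r <- set_enrichment_fisher(q, cat_set, univ)
  expect_gt(r$p_value, 0.4)
  expect_lt(abs(r$odds_ratio - 1), 0.3)

  # enriched overlap equals the hypergeometric tail by enumeration
  cat9 <- univ[c(1:9, 101:121)]
  r9 <- set_enrichment_fisher(univ[1:20], cat9, univ)
  tail9 <- sum(dhyper(9:20, 30, 170, 20))
  expect_equal(r9$p_value, tail9, tolerance = 1e-12)
  expect_equal(r9$overlap, 9L)

  # complete overlap has the product-form closed form
  small_u <- paste0("s", 1:12)
  rc <- set_enrichment_fisher(small_u[1:3], small_u[1:5], small_u)
  closed <- choose(5, 3) / choose(12, 3)
  expect_equal(rc$p_value, closed, tolerance = 1e-12)
  expect_error(set_enrichment_fisher("a", "a", character(0)), "empty universe")
})

test_that("hallmark enrichment applies Bonferroni across the hallmark family", {
  ann <- make_synthetic_compendium(120, seed = 56)
  query <- ann$symbol[1:25]
  res <- hallmark_enrichment(query, ann)
  expect_equal(nrow(res), length(unique(unlist(ann$hallmarks))))
  expect_equal(res$adjusted_p, pmin(1, res$p_value * nrow(res)))
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_true(all(res$overlap <= pmin(res$set_size, res$category_size)))
})

test_that("external consensus scores threshold at 1.5 for enrichment", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcancer\tscore", "A\tLUAD\t2.0", "B\tLUAD\t1.2",
               "C\tBRCA\t1.6", "D\tBRCA\t0.5"), f)
  cd <- read_consensus_driver(f)
  r <- consensus_driver_enrichment(c("A", "C", "E"), cd,
                                   universe = c(LETTERS[1:10]))
  expect_equal(r$overlap, 2L) # A and C pass score > 1.5
  expect_equal(r$category_size, 2L)
})
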