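# Independent oracles and fixture builders shared across the suite.

# Quadratic brute-force competition ranking: 1 + number of qualified genes
# strictly lower in (primary, secondary) lexicographic ascending order.
brute_competition_rank <- function(primary, secondary, qualified = primary >= 1) {
  score <- rep(NA_integer_, length(primary))
  pq <- primary[qualified]; sq <- secondary[qualified]
  for (i in which(qualified)) {
    score[i] <- 1L + sum(pq < primary[i] |
                           (pq == primary[i] & sq < secondary[i]))
  }
  score
}

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# support of the fixed-margin 2x2 family (probabilities from products of
# binomial coefficients; the relative tolerance matches the conventional
# tie rule for "as extreme").
fisher_enum_oracle <- function(n11, n10, n01, n00) {
  r <- n11 + n10
  c1 <- n11 + n01
  n <- n11 + n10 + n01 + n00
  amin <- max(0L, r + c1 - n)
  amax <- min(r, c1)
  support <- amin:amax
  logp <- lchoose(r, support) + lchoose(n - r, c1 - support) - lchoose(n, c1)
  pr <- exp(logp)
  obs <- pr[support == n11]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Gini coefficient from its definitional form: mean absolute difference
# over twice the mean.
gini_brute <- function(x) {
  if (sum(x) == 0) return(0)
  n <- length(x)
  mad_sum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) mad_sum <- mad_sum + abs(x[i] - x[j])
  mad_sum / (2 * n^2 * mean(x))
}

# Minimal cohort from explicit matrices (genes x samples), naming axes.
tiny_cohort <- function(sna, cna, expr_z = NULL, cancer_code = "TST", ...) {
  g <- sprintf("G%02d", seq_len(nrow(sna)))
  s <- sprintf("S%02d", seq_len(ncol(sna)))
  dimnames(sna) <- list(g, s)
  storage.mode(sna) <- "integer"
  dimnames(cna) <- list(g, s)
  storage.mode(cna) <- "integer"
  if (!is.null(expr_z)) dimnames(expr_z) <- list(g, s)
  cohort_omics(cancer_code, sna = sna, cna = cna, expr_z = expr_z, ...)
}

# Hand-rolled FASTQ writer for crafted read sets.
write_fastq <- function(reads, path) {
  recs <- character(4L * length(reads))
  idx <- seq_along(reads)
  recs[4L * idx - 3L] <- sprintf("@r%03d", idx)
  recs[4L * idx - 2L] <- reads
  recs[4L * idx - 1L] <- "+"
  recs[4L * idx] <- strrep("I", nchar(reads))
  writeLines(recs, path)
  path
}

random_spacer <- function(n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
}
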