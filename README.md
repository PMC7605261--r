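# epidriver

Pan-cancer multi-omics prioritization of epigenetic regulator driver genes.

## What this package does

Epigenetic regulator genes (ERGs) — the writers, editors and readers of DNA
methylation and histone marks, chromatin remodelers and helicases — are
recurrently disrupted across malignancies, by somatic mutation, by copy
number change, and through expression and promoter-methylation aberrations.
Deciding which of these disruptions mark genuine *epidrivers* (ERGs whose
deregulation contributes to tumorigenesis) requires integrating all of those
alteration channels across many cancer cohorts at once, plus orthogonal
functional evidence from knockout screens.

`epidriver` implements that integration as a tested, reusable pipeline over
cBioPortal-style gene×sample matrices:

- **Alteration landscape** — per-gene, per-cancer frequencies of
  nonsynonymous mutations (SNA) and GISTIC-coded copy-number alterations
  (CNA, −2…+2), with the deep-event regrouping, the 1% altered-gene
  threshold, the six-way category labels (`SNA`, `amp`, `amp_SNA`, `del`,
  `del_SNA`, `ma`), the twice-as-prevalent direction rule, and summaries
  stratified by the 12 ERG functional classes and by chromosome.
- **Expression integration** — |Z| > 2 aberration rates; Pearson correlation
  of CNA calls or mutation status with expression Z-scores filtered at
  R² > 30% / 10% with FDR < 0.05; promoter eQTM scanning (CpGs within
  −1000…+500 bp of the TSS, strand-aware) correlating methylation betas with
  expression; differential-expression post-processing (≥10 reads,
  |log10 FC| > 1, FDR < 0.05) and the two-sample up/down proportion test.
- **Driver scoring** — the package core. A competition-ranking engine
  (tied genes share a score; the next distinct gene skips by the tie-group
  size) applied to four tracks — SNA, CNA (direction-aware), expression
  Z-score, and fold change — where a gene's primary rank is the number of
  cancer types passing that track's frequency filter (5% of samples for
  SNA/CNA; 15% of samples with |Z| > 2; FDR < 0.05 with |log10 FC| > 1) and
  the secondary rank its mean qualifying alteration percentage. Tracks
  combine with weights 1 : 1 : 0.5 : 0.5 into the **Pan-Cancer Driver
  score** (ordinal position, 1 = strongest). A percentile-based
  **Multi-Omics Driver score** ranks genes within each cancer type. Fisher
  enrichment against external consensus-driver calls and the 10 cancer
  hallmarks (Bonferroni across hallmarks) rounds out the module.
- **Co-occurrence / mutual exclusivity** — per-cancer 2×2 odds ratios over
  altered samples (mutation, fusion, or deep CNA), Haldane–Anscombe
  corrected only when a cell is zero, two-sided Fisher exact p-values,
  BH FDR per cancer, and cross-cancer meta-averaging of significant ORs
  with the ≥5–10% joint-alteration filter.
- **CRISPR screen** — spacer counting from amplicon FASTQ (exact or
  mismatch-tolerant), library-representation QC (coverage, skew, Gini), a
  precision-weighted robust per-guide enrichment/depletion test,
  cross-method (p < 0.001 / p < 0.01) and cross-timepoint consensus
  hit-calling with Venn intersection counts, and the metastatic (M1) vs
  nonmetastatic (M0) mutation-frequency comparison for hit genes.
- **Synthetic cohorts** — a fully seeded generator producing multi-cancer
  `cohort_omics` objects with planted drivers, association pairs
  (target odds ratio via the Plackett construction), promoter eQTMs,
  differential expression, metastasis-linked mutations, and
  Dirichlet-multinomial screens with planted fold effects — every planted
  effect returned in truth tables, so each stage has a ground-truth
  acceptance surface.

## Worked example

```r
library(epidriver)

pd <- data.frame(gene = sprintf("ERG%04d", 1:2), cancers = "all",
                 sna_rate = 0.15, cna_rate = 0.15,
                 cna_direction = c("amp", "del"))
params <- simulation_params(n_cancers = 2, n_genes = 50,
                            samples_per_cancer = 100,
                            planted_drivers = pd, seed = 42)
sim <- simulate_multi_cancer_cohorts(params)

ds <- pan_cancer_driver_score(sim$cohorts)
head(ds[order(ds$pan_cancer_score),
        c("gene", "sna_primary", "cna_primary", "cna_direction",
          "combined", "pan_cancer_score")], 2)
#>      gene sna_primary cna_primary cna_direction combined pan_cancer_score
#> 1 ERG0001           2           2           amp        4                1
#> 2 ERG0002           2           2           del        2                2
```

The two planted drivers mutate and copy-number-alter ~15% of samples in both
synthetic cancers, so each qualifies in 2 cancer types on the SNA and CNA
tracks (`sna_primary = cna_primary = 2`); their combined weighted rank sums
put them at the top ordinal positions of the Pan-Cancer Driver score
(position 1 = strongest), while the 48 background genes qualify on no track
and carry no score. `multi_omics_driver_score(sim$cohorts[[1]])`
gives the complementary within-cancer percentile score (planted driver
ERG0001 scores 1.00 of a possible 1.0), and
`pairwise_association()` + `meta_cooccurrence()` recover planted
co-occurrence structure as `direction = "cooccur"` edges with their mean
significant odds ratio.

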