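---
title: "Methods: multi-omics prioritization of epigenetic regulator driver genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics prioritization of epigenetic regulator driver genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidriver)
```

## Scope and data model

`epidriver` integrates four alteration channels for epigenetic regulator
genes (ERGs) across cancer cohorts: somatic nonsynonymous mutations (SNA),
GISTIC-style gene-level copy-number calls (CNA, coded −2 deep deletion, −1
shallow loss, 0, +1 shallow gain, +2 deep amplification), expression
Z-scores, and promoter CpG methylation betas, plus pooled CRISPR knockout
screen counts as orthogonal functional evidence. A `cohort_omics` object
holds one cancer type's gene×sample matrices on a single shared gene axis.
Two semantics matter throughout: in mutation and CNA matrices, absence
means 0 (no alteration observed), matching cBioPortal export conventions;
in expression and methylation matrices, `NA` is genuinely missing and is
excluded from denominators, never coerced to zero. Genomic coordinates are
1-based inclusive.

Every numeric constant lives in one `analysis_thresholds()` object so no
cutoff is hard-coded at a call site; the lint-style test in the suite
checks behavior at each boundary.

## Alteration landscape

For category purposes CNAs are regrouped to deep events only: shallow
(±1) calls are too close to noise and ploidy artifacts to anchor a driver
claim, but they are retained in the `any_cna_frac` burden column used by
the chromosome-level summaries. At the sample level the six categories
(`none`, `SNA`, `amp`, `amp_SNA`, `del`, `del_SNA`) partition the
(mutation presence × CNA call) grid exactly. At the gene level, a gene is
altered in a cancer type when mutation, deep-amplification or
deep-deletion frequency reaches `altered_min_frac` (1%). When both CNA
directions qualify, the direction at least `twice_rule_ratio` (2.0) times
as prevalent as the other wins, otherwise the gene is `ma` (multiple
alterations). When a mutation signal coexists with one qualifying CNA
direction the label is decided by plurality over the sample-level
categories; the aggregation from sample categories to a gene label is a
genuinely open choice, and plurality was chosen for determinism, with ties
resolved to `ma`.

## Expression integration

Expression aberration is |Z| > `z_cut` (2.0). Alteration–expression
coupling is plain Pearson correlation — the CNA call as a numeric
predictor, or the mutated indicator, which makes the SNA track a
point-biserial correlation — filtered at R² > 30% (CNA) or 10% (SNA) with
BH FDR < 0.05. The FDR family is per cancer type and per track: the
results are reported per cancer, so correcting within that family matches
the reporting unit. Genes with fewer than 3 paired observations or a
constant predictor are kept as rows with an explicit `skip_reason` rather
than silently dropped.

The eQTM scan assigns a CpG to a gene when it lies within −1000…+500 bp of
the TSS *in transcription direction* (the window flips on the − strand).
Expression is `log2(count + 1)` by default: Pearson correlation on raw
RSEM-like counts is dominated by a handful of extreme values; a raw-counts
mode is available for literal reproduction of the classical description.
Per gene, the minimum-p CpG is flagged `is_top_for_gene`, with ties broken
deterministically by CpG identifier; a CpG falling in two genes' windows is
tested against both.

Differential expression post-processing removes genes with under
`de_min_reads` (10) total reads, |log10 FC| ≤ `logfc_cut`, or
FDR ≥ 0.05. Fold changes are carried in log10 (the convention of the
source analyses); `logfc_cut` defaults to 1.0 with 2.0 as the stricter
documented alternative. The built-in `nb_wald_de()` — a negative-binomial
Wald test with median-of-ratios size factors and method-of-moments
dispersion — exists so the pipeline runs self-contained; it is a declared
built-in, not a re-implementation of external DE tools, and external DE
tables can be supplied wherever one is consumed. The up/down proportion
test compares the up-regulated fraction between two gene sets with the
pooled two-proportion z statistic; whether the comparison is two-sample
(ERGs vs all genes) or one-sample against 0.5 is ambiguous in the source
description, so the two-sample reading is the default and a one-sample
binomial mode is provided.

## Driver scoring

`competition_rank()` implements competition ("min") ranking on the
lexicographic (primary, secondary) key: x genes tied on both keys at score
y all receive y and the next distinct gene receives y + x. Genes that
qualify nowhere receive no score rather than a default rank.

The Pan-Cancer Driver score builds four such rankings:

| track | primary count | secondary | filter |
|-------|---------------|-----------|--------|
| SNA | cancers with sna_frac ≥ 5% | mean qualifying frac | `driver_freq_min_frac` |
| CNA | cancers with deep frac ≥ 5%, per direction | mean qualifying frac | direction with more qualifying cancers wins; ties by mean frequency |
| Z | cancers with |Z|>2 fraction ≥ 15% | mean qualifying fraction | `z_sample_frac` |
| FC | cancers with FDR < 0.05 and \|log10 FC\| > 1 | mean qualifying \|log10 FC\| | cancers lacking normals contribute nothing |

The four ranking scores combine as a weighted sum with weights 1 (SNA),
1 (CNA), 0.5 (Z), 0.5 (FC) — the two expression tracks measure the same
biological phenomenon, so they share the weight of one genetic track. Two
design points were genuinely open and are resolved as follows. First, the
secondary key aggregates "the percentage of samples" across qualifying
cancers as the mean (not the max), for stability. Second, a gene
unqualified on a track contributes 0 to the combined sum rather than a
minimum rank, so a strong single-track driver is not drowned by three
absent tracks. The final `pan_cancer_score` is the ordinal position by
descending combined sum (1 = strongest, ties share the smaller position);
the raw combined sum is also emitted.

The Multi-Omics Driver score is the equal-weight mean of the within-cancer
percentile ranks (rank/n, ties averaged) of mutated fraction, deep-CNA
fraction (larger direction), and |Z|>2 fraction. The exact functional form
of the original multi-omics weighting is not fully pinned by its published
description; this percentile-mean definition is the package's documented
stand-in and is flagged as such here and in the function documentation.

Set enrichment uses the one-sided Fisher exact test with the sample odds
ratio of the implied 2×2 table; hallmark enrichment corrects across the 10
hallmarks with Bonferroni. The background universe for enrichment against
external consensus-driver calls is a required argument — the published
analysis never states its universe, so no specific p-value is asserted as
reproducible.

## Co-occurrence and mutual exclusivity

A sample is altered for a gene if it carries a nonsynonymous mutation, a
fusion, or a deep CNA. Per pair and cancer the odds ratio is
(n11·n00)/(n10·n01) with the Haldane–Anscombe correction (0.5 added to all
four cells) applied only when a cell is zero; the two-sided Fisher exact
p-value is computed on the *uncorrected* table; BH FDR is per cancer
(analysis per cancer type, then meta-analysis). Significant (FDR < 0.05)
ORs are averaged across cancers on the natural scale — as the source
procedure describes — with a geometric-mean option, since arithmetically
averaging ORs on both sides of 1 is distortive. Co-occurrence candidates
(OR > 1) must additionally have both genes altered together in
≥ `cooc_min_frac` (5%, or 10% for the stricter variant) of samples; that
filter would by construction suppress exclusivity calls, so pairs with
OR < 1 are instead required to have each gene's marginal altered fraction
above the same cut. A pair's direction is `cooccur` when all surviving ORs
exceed 1, `exclusive` when all are below 1, `mixed` on disagreement,
`none` when nothing survives.

## CRISPR screen

Reads are assigned to guides by exact spacer substring match in the
as-sequenced orientation by default (the amplicon design fixes
orientation); 1-mismatch and reverse-complement modes are provided for
real data. Reads matching more than one guide are discarded as ambiguous,
and read accounting is conserved (mapped + ambiguous + unmapped = total).

`test_guides()` is the package's self-contained guide test: counts are
normalized by median-of-ratios size factors, the per-guide log2 late/early
ratio (+0.5 pseudocount) is centered on the library median (the null is
that most guides are unchanged), divided by its delta-method sampling
standard deviation — so low-abundance guides, whose ratios are noisier,
are not over-called — and rescaled by the MAD of those standardized
statistics to absorb overdispersion; p-values come from the normal
reference with BH adjustment. It is a declared substitute for external
count-model tools, and external per-guide p-value tables can be fed
directly to `consensus_hits()` to mirror a two-package design.

Consensus calling requires a guide to pass every supplied method's
threshold (defaults 0.001 and 0.01) with one direction; a gene is a
candidate when at least one of its guides (configurable to two) is a
consensus hit in every required timepoint comparison with a consistent
direction. Genes whose guides disagree in direction across comparisons are
reported as `mixed` and excluded from candidates — the source procedure
does not state how such genes are handled, and exclusion is the
conservative choice. The M1-vs-M0 comparison averages per-cancer mutation
frequencies unweighted across cancer types contributing both subsets; the
pooled Fisher test on summed counts is labeled exploratory because no test
is part of the original comparison.

## Synthetic cohorts: what they emulate, and what they do not

The generator plants known signal into otherwise unstructured background:

- mutations are Bernoulli per gene and sample (background rate 1%);
- deep CNAs are contiguous blocks along each chromosome's gene order
  (geometric block length, mean 3 genes) nested inside shallow blocks
  (±2 genes), emulating focal-within-broad structure; seed positions
  extend virtually upstream of each chromosome so the marginal deep rate
  is position-independent;
- expression follows Z = a·CNA + ε with a = 0.8, ε ~ N(0, 0.5), so the
  population R² of the CNA–expression correlation is
  a²·Var(CNA)/(a²·Var(CNA) + σ²), an analytic target the tests check;
- planted association pairs are drawn from the Plackett joint distribution
  with the requested odds ratio and marginal altered rate (default 0.2;
  the acceptance checks use 0.3, a realistic altered fraction for commonly
  disrupted driver pairs and one at which a 200-sample cohort has adequate
  per-cancer power for exclusivity);
- planted eQTM CpGs couple logit(beta) linearly to standardized
  log2-expression with the requested sign and strength; background
  promoter CpGs are independent Beta(2,2) noise;
- tumor/normal counts are negative binomial (dispersion φ = 0.1,
  lognormal library factors) with planted log2 effects;
- screens draw day-0 counts Dirichlet-multinomial (concentration 3) and
  multiply planted guides' proportions by their fold effect at later
  timepoints; FASTQ emission embeds each spacer in fixed flanks with read
  multiplicity equal to the count table, so re-counting is an exact
  identity.

One global seed with named substreams per matrix makes outputs
byte-reproducible, and adding a new matrix never perturbs existing ones.
The truth tables are the single source of planted signal; no analysis
function reads them.

Deliberately not emulated: empirical mutation spectra and trinucleotide
signatures, real chromosome lengths and gene densities, arm-level
aneuploidy patterns, tumor purity and subclonality, batch structure, and
measurement error in methylation arrays. Passing the planted-recovery
tests therefore shows the statistics and rules are implemented correctly
and calibrated under clean conditions — not that the pipeline is robust to
every artifact of real TCGA data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant predictors and
sub-3-sample pairs are skipped with reasons; all-missing expression rows
give `NA` rates; an all-zero screen condition yields Gini 0; zero-total
proportion groups are errors. Ties are broken deterministically
throughout (lexicographic gene order, smallest ordinal position, CpG id).
Odds ratios use the 0.5 correction only in the presence of a zero cell, so
non-degenerate tables are untouched.

The test suite and acceptance script run at desk scale, chosen so each
check has clear power while the whole suite stays fast: driver recovery
uses 6 cancers × 300 genes × 200 samples with 5 planted drivers at 10–20%
alteration rates against 1% background; pair recovery uses 6 cancers of
200 samples with planted odds ratios 8 and 0.1; the normal-tail check uses
10⁵ draws; screens use a 426-gene, 1–4-guides-per-gene library at 10⁵
reads per condition with 16-fold planted effects. Exact-agreement checks
(Fisher p vs full hypergeometric enumeration) run exhaustively for all
2×2 tables up to n = 25 and on a 2000-table random sample up to n = 60.

## Known limitations

- The Multi-Omics Driver score is a documented stand-in definition (see
  above), suitable for ranking within a cancer type but not guaranteed to
  match any externally published score values.
- The built-in DE and guide tests are intentionally simple; for
  publication-grade single-dataset analyses, supply tables from dedicated
  count-model tools — the consensus and post-processing layers accept
  them directly.
- Fisher/OR co-occurrence does not model mutation burden covariation
  between genes; highly mutated samples can induce spurious co-occurrence
  in real data (the synthetic null has no such structure).
- Expression Z-scores are consumed as given; no attempt is made to
  distinguish Z-score reference flavors (vs-diploid vs all-samples).
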