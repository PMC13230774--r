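---
title: "Rare-variant burden testing for congenital heart disease: models, calibration and design choices"
author: "chdburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chdburden)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
the numerical conventions, and the places where the design was genuinely
open and a choice had to be made.

## The scientific setting

Congenital heart disease (CHD) affects roughly 1–2% of live births and a
substantial fraction of cases remain genetically unexplained. At the
allele frequencies relevant for high-penetrance disease (minor allele
frequency below 10⁻³) single-variant association has essentially no
power, so the field collapses rare variants within a unit — a gene, or a
gene set — into a single carrier or allele-count statistic and compares
cases against controls. This package implements that collapsing
framework for a cohort stratified into syndromic (sCHD: extracardiac
malformations or neurodevelopmental involvement) and non-syndromic
(nsCHD) cases, with three analysis tiers: per-gene Fisher exact burden,
gene-set logistic burden, and calibration diagnostics built around
synonymous variants as a negative control.

Upstream steps — alignment, variant calling, functional annotation,
relatedness pruning and ancestry PCA — are out of scope; their outputs
(consequences, a LOFTEE-style high-confidence loss-of-function flag,
CADD/REVEL/MVP scores, multi-source allele frequencies, genotype quality
fields, ancestry PCs) are consumed as columns of the input tables.

## Variant categories

Variants are assigned to exactly one of four categories, in order of
precedence:

* **hcLOF** — consequence in {stop-gained, frameshift, essential splice}
  *and* the high-confidence flag set. The flag is produced upstream; the
  package only gates on it.
* **missC** — missense variants called likely deleterious by at least 2
  of 3 scores at inclusive thresholds: CADD ≥ 24, REVEL ≥ 0.5,
  MVP ≥ 0.8. A missing score counts as *not passing* — the conservative
  option, which never promotes an unscored variant.
* **synonymous** — the negative-control category.
* **none** — everything else (including missense failing the ensemble
  rule and low-confidence LOF).

Two conventions here were open and are fixed as follows. First, score
thresholds are inclusive (≥): the customary reading of integer-valued
CADD cut-offs. Second, category precedence puts hcLOF above missC, which
only matters for annotation edge cases since the consequence sets are
disjoint.

The threshold-selection machinery that justified the ensemble is part of
the package (`select_score_thresholds()`): per candidate score, a
rank-based (midrank) ROC AUC is computed separately in LOF-constrained
genes (LOEUF < 0.35) and non-constrained genes (LOEUF ≥ 0.35); a score
qualifies when both AUCs exceed 0.9, and its working threshold is the
point maximising Youden's J = sensitivity + specificity − 1 on the
pooled labelled set, with ties resolved to the smallest qualifying
threshold so the result is deterministic. "Optimal threshold" is not
further specified anywhere authoritative; Youden's J is the standard
reading. An MPC-style column may be supplied and is evaluated like any
other score, but classification never consults it.

**Rarity.** A variant is rare when *every present* allele-frequency
source — the internal cohort AF plus up to four external references — is
strictly below `rare_maf` (default 10⁻³). Absent sources impose no
constraint; missing AF is never conflated with zero, because the two have
different rarity semantics. Multi-allelic sites are split into biallelic
records before the filter (split-then-filter).

## Per-gene burden model

**Genotype QC.** A call is high-confidence when DP ≥ 10, GQ ≥ 20 and —
for heterozygous calls only — allelic balance strictly greater than 0.2.
Missing zygosity always fails.

**Carriers.** Under the dominant model a carrier has ≥ 1 QC-passing
heterozygous or hemizygous genotype at a rare variant of the category in
the gene, counted at most once per (gene, category). Hemizygous male
X-chromosome genotypes count as carriers: without this, X-linked genes
are untestable in males. Homozygotes are deliberately *not* dominant
carriers; they belong to the recessive analysis.

**Test.** For each gene and case stratum the one-sided Fisher exact test
(exact hypergeometric tail toward case enrichment, computed via
`stats::phyper`) is applied separately to hcLOF and missC carrier
counts, and the per-gene statistic is P = min(P_lof, P_miss), with ties
labelled hcLOF (the more severe category; deterministic output). The
discovery direction is excess in cases, hence one-sided. Genes with no
rare hcLOF or missC variant site contribute nothing — this is why the
tested-gene count is smaller than the annotated-gene count.

**Correction.** The study-wide family is n = n_genes × 2 tests (two
categories per gene; 2 × 16,351 = 32,702 at study scale). Bonferroni is
min(1, P·n). The BH step-up assigns the gene at ascending rank i within
its *stratum's* list the value min over j ≥ i of min(1, P₍ⱼ₎·n/j) —
ranks local, multiplier global. This scheme is exactly
`stats::p.adjust(p, "BH", n)` and reproduces every published adjusted
value in the bundled top-genes fixture (`chd_table1()`) from the printed
minimal p-values alone, including the tie block and the step-up minimum
that pulls a rank-6 gene below its raw rank value. Three Bonferroni
cells and one BH cell of the printed table differ in the last printed
digit when recomputed from the *rounded* minimal p — an artefact of the
published rounding, not of the scheme.

**Recessive analysis.** A recessive carrier has ≥ 1 QC-passing
homozygous rare protein-altering genotype in the gene, or ≥ 2 *distinct*
QC-passing rare heterozygous protein-altering variants in it — the
unphased proxy for compound heterozygosity, a declared approximation
(without phase, two hets in cis are indistinguishable from trans).
"Protein-altering" means the hcLOF and missC categories, keeping the
recessive analysis on the same qualifying-variant footing as the
dominant one. Hemizygous calls are not recessive carriers under this
rule; that is a recognised limitation for X-linked recessive
architecture.

## Gene-set burden model

Genes are ranked ascending by a constraint metric (LOEUF for
loss-of-function, MOEUF for missense; lower = more constrained) and cut
into `n_bins = 10` contiguous near-equal bins (sizes differ by at most
one, remainder to the first bins; ties broken by gene id). Alternatively
sets are supplied directly, e.g. differentially-expressed-gene clusters
C0–C14 from an embryonic-heart single-cell atlas.

Per sample, the minor allele count (MAC) over a set is the sum of
dosages (het 1, hom 2, hemizygous 1) across QC-passing genotypes at rare
variants of one category within the set's genes. The burden test is a
maximum-likelihood logistic regression of case status on MAC with the
five ancestry PCs and sex as covariates (IRLS, |Δdeviance| < 10⁻⁸,
≤ 100 iterations), reporting OR = exp(β), the 95% Wald interval and the
Wald p. Degenerate inputs (no MAC variation), non-convergence and
quasi-separation (SE > 10 or |β| > 15) are flagged on the result rather
than silently reported; no Firth correction is applied, matching the
plain-logistic convention of the field. Unknown sex is imputed to the
cohort majority and counted on the result — dropping those samples would
silently change stratum sizes.

The battery runs one test per (set, stratum) in each category, with
aCHD pooling both case strata, and applies a per-category Bonferroni
family of #sets × #strata (45 for 15 clusters × 3 strata). The
constraint-bin battery uses the same rule with its own family size
(n_bins × #strata), by analogy — no authoritative correction is stated
for the bins.

## Calibration

* `lambda_gc(p)` — median of the 1-df χ² quantile transform divided by
  the χ²₁ median (≈ 0.4549). A fully degenerate discrete vector (all
  p = 1) yields λ = 0, which is propagated rather than erroring.
* `lambda_1000(λ, n₁, n₀) = 1 + (λ − 1)(1/n₁ + 1/n₀)/(2/1000)` — the
  standard equal-arm rescaling; linear in λ, fixed point at λ = 1,
  identity at arm sizes 1000.
* QQ expected quantiles follow −log₁₀((i − 0.5)/n) for ascending
  observed p — fixed convention, also used by the QQ plot.
* `permutation_null()` permutes case/control labels (stratified mode,
  the default, preserves the sCHD/nsCHD split — closer to the study
  design; unstratified mode preserves only the case total), re-runs the
  chosen pipeline per permutation, and reports the permutation
  distribution of λ with the observed value's percentile. The default
  permutation count is 100 and everything is reproducible from the seed.
* `maf_stratified_synonymous()` recomputes synonymous gene-level p
  restricted to variants in each MAF bin. Variants are binned on the
  maximum AF across present sources (the same quantity the rarity filter
  bounds) with the first bin closed on the left, so every rare
  synonymous variant lands in exactly one bin, including AF-0
  singletons.

A caveat worth stating plainly: with per-gene carrier rates around 10⁻³
and realistic arm sizes, one-sided Fisher p-values are heavily discrete
and conservative — most genes have zero case carriers and p = 1 — so λ
computed on them sits well below 1 and "λ ≈ 1" is *not* the correct null
expectation at the gene level. The package's calibration tests therefore
assert direction (no inflation) and permutation coverage, which respect
the discreteness, rather than a λ = 1 point target. The published
real-data inflation estimate (λ₁₀₀₀ of 1.04–1.05) requires the
access-controlled cohort and is not reproducible here; it motivates the
diagnostics, nothing more.

## Bulk expression profiling

Per-gene mean RPKM is taken over samples inside an inclusive
developmental window (default 4–8 weeks post-conception) per tissue;
percentile ranks use the midrank convention 100·(rank − 0.5)/n, which is
invariant under monotone transforms of expression. Two gene sets are
compared per tissue by the two-sided Wilcoxon rank-sum test on the
percentiles (exact null for combined n ≤ 20 without ties, normal
approximation with continuity correction otherwise), Bonferroni-corrected
over the tissues tested. Whether the comparison should use percentiles
or raw means was unspecified; percentiles are consistent with the
ranking step that precedes it.

## The synthetic-data generator

`simulate_cohort()` produces cohorts with the statistical structure the
analyses assume. Defaults are the study conditions: 1818 sCHD and 2929
nsCHD cases, 52,881 controls, 19,923 genes. Constraint metrics are
log-normal (LOEUF: meanlog log 0.8, sdlog 0.6 — median 0.8 with a
realistic 0.2–2.5 spread; 2% missing). Each gene carries guaranteed
qualifying sites (one hcLOF, one passing missC, one rare synonymous)
plus Poisson-distributed extra sites whose flags, scores and AFs are
drawn from class-conditional models; allele frequencies follow a
rare/common point-mixture (weight 0.9 below the rarity threshold) with
bounded per-source jitter so the rare/common split survives
multi-source filtering. Genotype quality fields are negative-binomial
depth (size 20, mean 60), clamped Gaussian GQ (mean 80, SD 15) and
Beta(20, 20) heterozygous allelic balance, so a small realistic fraction
of calls fails QC.

Effects are planted on the per-gene *carrier probability* — for a
planted (target, category, stratum, OR) the case carrier probability is
logit-shifted by log OR from the baseline rate — matching the
alternative hypothesis of a carrier-based test. The baseline per-gene
per-category carrier rate defaults to 10⁻³, a realistic per-gene rare
carrier frequency; it is a single choice made once. Carriers are drawn
per gene × category × stratum as Binomial counts and assigned to
sampled individuals, so cost scales with carriers, not samples ×
variants, and the study-scale default remains tractable. PCs are
standard normal and independent of status by default; a confounding mode
shifts case PC1 to exercise covariate adjustment.

What the generator does *not* emulate: linkage disequilibrium, realistic
site-frequency spectra beyond the two-component mixture, sequencing
reads, batch or capture-platform artefacts, and population substructure
beyond the optional PC1 shift. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under the stated
model — not that real-cohort confounding is handled; that is what the
calibration module is for on real data.

`simulate_labeled_scores()` generates the benign/pathogenic score table
for the ROC step from a shared latent deleteriousness axis (so scores
are mutually correlated), including a deliberately weaker `mpc` column
that the vetting step should reject at moderate separation.
`simulate_deg_clusters()` builds the 15 cluster sets; when risk genes
are supplied, exactly one named cluster overlaps them and all others
avoid them, so planted burden effects propagate to exactly one cluster.
`simulate_expression()` draws log-normal RPKM with per-gene-per-tissue
baselines (SD 1) dominating observation noise (SD 0.5), making a
1-SD-unit planted shift detectable at the set sizes used in the tests
while keeping tissues exchangeable under the null.

## Problem sizes used by the tests and the acceptance script

Test cohorts are scaled down from the study defaults so the whole suite
runs quickly while keeping every assertion adequately powered — the
sizes are stated here as the package's own choices. Null family-wise
error uses 20 cohorts of 150 + 150 cases vs 1200 controls over 250
genes; power checks use up to 2000 cases vs 20,000 controls over
300–1200 genes; the end-to-end run uses 1000 + 1000 cases vs 8000
controls over 1500 genes with OR 2.27 planted in the top LOEUF decile
for sCHD (the magnitude mirrors the bin-1 syndromic estimate reported
for the real cohort, which is itself not desk-reproducible). Logistic
parameter recovery uses 200 replicates at 5000 expected cases among
25,000 samples. For λ-based permutation diagnostics the per-gene carrier
rate is raised to 5 × 10⁻³ — at the default rate the median synonymous
p is exactly 1 and λ degenerates, as discussed above. Likewise the
null-trend property across constraint bins is checked at 400 cases /
2500 controls / 500 genes with a 2 × 10⁻³ carrier rate: with only a
handful of carrier events per bin, zero-count bins yield extreme
negative log-ORs and any bin-size imbalance masquerades as a trend.

## Known limitations

* Compound heterozygosity is approximated without phase; two hets in
  cis are counted as a recessive carrier.
* Hemizygous genotypes do not enter the recessive model.
* The per-gene Fisher test is unadjusted for covariates by design; only
  the gene-set logistic tier adjusts for ancestry and sex.
* Quasi-separation in the logistic tier is flagged, not penalised.
* Post-QC stratum sizes are data, not constants: published per-gene
  p-values cannot be regenerated from headline cohort sizes because the
  final analysed sizes after genotype-level QC are not published; the
  multiple-testing arithmetic, which is exactly reproducible, is what
  the acceptance machinery checks.
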