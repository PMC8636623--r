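---
title: "Methods: immune-selection mutation profiling and pooled screen statistics"
author: "immunoedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-selection mutation profiling and pooled screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoedit)
```

## The biological question

A tumor cell line engrafted into hosts with different levels of T cell
immunity is a natural selection experiment: clones carrying mutations that
blunt T cell recognition or killing expand preferentially under immune
pressure and are invisible in its absence. Comparing the clonal
composition of tumors grown in immunodeficient hosts, immunocompetent
hosts, and immunocompetent hosts receiving checkpoint blockade (anti-PD-1
or anti-PD-L1) therefore reads out candidate immune-evasion genes directly
from sequencing data, and further separates candidates whose advantage is
erased by restoring the PD-1 axis blockade response (PD-1-dependent) from
those that keep their advantage under blockade (PD-1-independent).
This package implements the two analysis arms of that design — the
allele-frequency hotspot filter and the statistics of the follow-up pooled
CRISPR knockout screens — together with a seeded synthetic-data generator
so every stage can be validated against planted ground truth.

## Hotspot mutation filter

For each variant in each sample the allele frequency is
AF = alt depth / total depth (`computeAF()`); a site with zero total depth
carries no evidence and is assigned AF 0. A site is *positive* in a sample
when AF ≥ 0.1 (`callStatus()`; the rule-table convention uses ≥, and the
comparator is exposed as `boundary = "ge"/"gt"` because a strict reading
is also defensible). `classifyHotspots()` then applies the cross-cohort
rules:

* negative in **every** in vitro baseline and **every** immunodeficient
  tumor;
* positive in **at least two** distinct immunocompetent tumors;
* category **PD-1-dependent** when negative in every checkpoint-blockade
  tumor of both antibody arms, **PD-1-independent** when positive in at
  least one.

A variant absent from a sample's table is treated as negative there — a
convention the joint-calling upstream makes natural but that must be
stated for per-sample tables. Variant identity is the exact `variant_id`
string; no positional merging is attempted. One subtlety found while
property-testing the filter: the number of reported hotspots is *not*
globally monotone in the AF threshold, because a higher threshold can also
clear a baseline positive and release a previously excluded variant;
monotonicity holds exactly when baseline samples carry no alternate reads.

## Screen statistics

**Normalization.** Normalized reads per sgRNA =
(reads per sgRNA / total mapped reads in the sample) × (max mapped-read
count among all samples) + 1. The max is taken over all samples loaded in
the comparison set, baselines included. The +1 pseudo-count floors every
value at 1 and keeps zero-count guides testable; within a sample the
transformation is affine and therefore rank-preserving.

**Dispersion.** Replicate screens are overdispersed relative to Poisson.
With per-replicate counts modelled as NB(mean μ_g, dispersion φ), the
within-condition likelihood conditional on the replicate sum does not
involve μ_g, so φ can be estimated by maximizing the summed conditional
log-likelihood over all guides (common dispersion, `estimateDispersion()`).
Optional tagwise values maximize each guide's conditional likelihood plus
`shrinkageWeight` times the average likelihood — an empirical-Bayes
weighted combination that pulls noisy per-guide estimates toward the
common value. The optimizer works on δ = φ/(1+φ) over [1e-4, 0.95]; an
all-constant matrix short-circuits to φ = 0, and a design with no
replicated condition returns a configurable fallback with a warning.

**Exact test.** Per guide, normalized counts are summed within each
condition into pseudo-counts (rounded to integers) and the group-A sum is
tested against the group-B sum conditional on the total. Because
normalization equalizes per-sample effective sizes, both group sums are
negative binomial with a shared success probability, and the conditional
law of the split given the total is exactly beta-binomial
(s; n_A/φ, n_B/φ) — the NB mean cancels. `nbExactTest()` evaluates this
closed form and obtains a two-sided p by the minimum-likelihood rule:
summing the probabilities of all splits at most as likely as the observed
one (with a 1e-8 relative tie tolerance). φ = 0 reduces to the conditional
binomial test. The test suite verifies the kernel against an independent
enumeration of negative-binomial probability ratios for every split with
total ≤ 50 and against a reference implementation of the same test family.

**Gene aggregation (α-RRA).** Guides are ranked by one-sided evidence in
the chosen direction (two-sided p halved when the fold-change sign
matches, 1 − p/2 otherwise — matching guides always rank above
non-matching ones) and converted to percentiles u = rank/m. For a gene
with k guides, ρ = min over its guides with u ≤ α of the Beta(j, k−j+1)
CDF at the j-th smallest percentile; a gene with no guide below α scores
ρ = 1. α defaults to 0.25 (the algorithm's customary choice; the method
description names the algorithm but not α). Significance comes from
permuting the guide-to-gene assignment, preserving per-gene guide counts:
perm_p = (1 + #{ρ_perm ≤ ρ_obs}) / (n_perm + 1), which is never smaller
than 1/(n_perm+1) and is bit-reproducible under a fixed seed. Because ρ
depends on the p-values only through their ranks, it is invariant under
any strictly monotone transform of the guide p-values.

**Hit calling.** `callHits()` applies fold-change and p cut-offs with two
presets matching the screen read-outs: in vivo (|FC| > 1.5, P < 0.05,
both directions) and co-culture (FC > 1.4, P < 0.05, enrichment only).
Raw p-values are used at screen level, matching the read-out convention;
BH adjustment is available (`adjust = "BH"`) to mirror the RNA-seq-style
criterion. `competitionLog2FC()` reports the per-guide log2 ratio of mean
normalized abundance for competition assays.

## Infiltration correlation

The cytotoxic infiltration score is the per-sample arithmetic mean of
CD8A, CD8B, GZMB and PRF1 expression (`cytotoxicScore()`); cohorts are
stratified at the 75th percentile of that score, "high" meaning strictly
above the linearly interpolated quantile (`stratifyByScore()`). Spearman
correlations use mid-ranks for ties; the two-sided p comes from the
t-approximation, replaced by exhaustive permutation for tie-free samples
below n = 10 (`spearmanAssoc()`). `panCohortVolcano()` runs one
correlation per cohort — against a second gene, the cytotoxic score, or a
supplied per-sample abundance vector (externally deconvolved T cell
abundances are consumed, never recomputed) — and flags significant
negative correlations (ρ < 0 and p < 0.05). Note the calibration
consequence: under independence ~5% of cohorts reach p < 0.05, so the
signed negative flag fires at about half that rate. Expression is used on
its input scale; rank statistics are invariant to monotone transforms, so
no log transform is applied. `mutationPrevalence()` reproduces printed
cohort prevalences with half-up rounding to one decimal (e.g. 19/399 →
4.8).

## The synthetic cohort generator

`simulateClonalCohort()` emulates the selection structure the filter
assumes. Defaults are the study design: 1 cultured baseline, 10
immunodeficient, 13 immunocompetent and 8 checkpoint-blockade tumors
(split 4/4 between the two antibody arms, the most even split of an
unstated allocation). Each site has a clone fraction per group: planted
drivers default to 0.4 where selected and 0.01 elsewhere, with
PD-1-dependent drivers low in *all* blockade tumors (eliminated once the
checkpoint is released) and PD-1-independent drivers high in both
immunocompetent and blockade tumors; passengers sit at 0.01 everywhere.
Total depth per site is NB(mean 100, dispersion 0.05) — deep
transcriptome coverage with mild site-to-site overdispersion — and alt
depth is binomial in the (slightly jittered, SD 0.005) clone fraction.
Clone fraction acts directly as the binomial success probability; tumor
purity and subclone phylogeny are not modelled separately, and no
read-level data are simulated.

`simulateScreenCounts()` emulates the targeted knockout screens: 58 genes
× 10 guides (the 5 checkpoint-pathway control genes included), log-normal
baseline abundance (log-SD 0.5), per-guide knockout efficacy drawn once
from Beta(4, 1) (mean 0.8, so a typical gene shows most but not all of
its guides responding) and reused across conditions, expected abundance
baseline × effect^efficacy renormalized to a 3×10⁵-read sample, and
NB(dispersion 0.2) sequencing noise over 8 replicates per condition.

What passing recovery tests shows — and does not. The generator matches
the analysis model family (binomial AFs, NB counts), so recovery and
calibration results validate the *implementation* of the statistics and
the internal consistency of the pipeline. They do not establish
robustness to what real data add: index hopping and mapping artefacts,
purity variation, clonal interference between drivers, guide off-target
effects, or depth that covaries with expression.

## Numerical choices and problem sizes

* Exact-test p-values enumerate the full conditional support; ties in the
  minimum-likelihood rule use a 1e-8 relative tolerance.
* The dispersion optimizer's δ grid bounds φ to [1e-4, ~19]; the Poisson
  boundary is reported as-is (≈1e-4 ≈ 0).
* Permutation p-values use the add-one estimator, so they are never 0;
  all randomness is namespaced through explicit seeds and the caller's
  RNG state is restored.
* Writers format floating point at 6 significant digits and JSON is
  written without rounding, so reruns with one seed are byte-identical.
* Validation suites run at deliberately desk-sized problems chosen to
  make Monte-Carlo bands tight without being wasteful: 1000-guide null
  screens, 200/100-seed recovery sweeps, 1000 random cohorts against the
  brute-force oracle, and exhaustive enumeration up to 8-guide sets for
  the permutation comparison.

## Known limitations

* The hotspot filter treats variant IDs as opaque strings; recurrent
  mutations at different positions of one gene are separate hotspots
  (gene-level counts come from `summarizeHotspots()`).
* The exact test collapses replicates into pseudo-counts under the
  equal-effective-size assumption that normalization establishes; designs
  with wildly unequal per-sample depth dilute that approximation.
* Gene ranking reports RRA ρ with permutation p and median log2FC; no
  fusion with regression-style beta scores is attempted, since the
  combination rule for such a fusion is underdetermined.
* `spearmanAssoc()`'s exact mode enumerates n! orderings and is
  intentionally capped below n = 10.
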