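# immunoedit

Profiling somatic mutations selected by host T cell immunity, and the
statistics of the pooled CRISPR screens that follow them up.

## What this package is for

When a tumor cell line is engrafted into hosts with graded T cell
pressure — immunodeficient hosts, immunocompetent hosts, and
immunocompetent hosts under anti-PD-1/anti-PD-L1 checkpoint blockade —
clones carrying immune-evasion mutations expand only where that pressure
exists. `immunoedit` turns the resulting per-tumor variant tables and
sgRNA count matrices into candidate gene lists:

* **Hotspot filter.** A variant with allele frequency
  AF = alt depth / total depth is *positive* when AF ≥ 0.1. A hotspot
  must be negative in every cultured baseline and every immunodeficient
  tumor, and positive in ≥ 2 distinct immunocompetent tumors. Hotspots
  negative in every checkpoint-blockade tumor are **PD-1-dependent**
  candidates (presumably purged once T cells are re-armed); those
  positive in ≥ 1 blockade tumor are **PD-1-independent**.
* **Screen statistics.** Normalized reads per sgRNA =
  reads/sample total × (max sample total) + 1; negative-binomial
  dispersion by conditional maximum likelihood with empirical-Bayes
  tagwise shrinkage; per-guide two-sided conditional NB exact test
  (beta-binomial kernel, minimum-likelihood p); gene ranking by modified
  robust rank aggregation, ρ = min_j Beta CDF(u₍ⱼ₎; j, k−j+1) over guides
  with percentile u ≤ α, with permutation p-values; hit calling at
  |FC| > 1.5, P < 0.05 (in vivo preset) or FC > 1.4 (co-culture preset).
* **Infiltration correlation.** Cytotoxic score = mean(CD8A, CD8B, GZMB,
  PRF1) per sample, 75th-percentile stratification, Spearman
  correlations (exact below n = 10) and pan-cohort
  significant-negative-correlation summaries; printed-style mutation
  prevalences such as 19/399 → 4.8%.
* **Synthetic truth.** Seeded generators for cohort variant tables
  (group-specific clone fractions, binomial read sampling over
  overdispersed depths) and screen counts (log-normal baselines, per-guide
  knockout efficacy, NB noise) with ground truth, so the whole pipeline is
  testable without external data.

## Worked example

```r
library(immunoedit)

## cohort arm: simulate the engraftment design and profile hotspots
sim <- simulateClonalCohort(cohortSimConfig(seed = 1))
hs  <- classifyHotspots(sim$cohort)
as.data.frame(hs)[, c("variant_id", "gene", "category", "n_support")]
#>       variant_id    gene        category n_support
#> 1 chr1:10137:A:C DrvDep1   PD1_dependent        13
#> 2 chr2:10274:C:G DrvDep2   PD1_dependent        13
#> 3 chr3:10411:G:T DrvDep3   PD1_dependent        13
#> 4 chr4:10548:T:A DrvInd1 PD1_independent        13
#> 5 chr5:10685:A:C DrvInd2 PD1_independent        13
#> 6 chr6:10822:C:G DrvInd3 PD1_independent        13
```

All six planted drivers are recovered with the right category (each
positive in all 13 immunocompetent tumors), and none of the 50 passenger
sites pass the filter.

```r
## screen arm: planted threefold enrichment of Gene001
scr  <- simulateScreenCounts(screenSimConfig(
          geneEffect = list(selected = c(Gene001 = 3)), seed = 2))
nrm  <- normalizeCounts(scr$counts)
disp <- estimateDispersion(nrm)
disp
#> DispersionEstimate: common phi = 0.2017
res <- nbExactTest(nrm, "reference", "selected", phi = phiCommon(disp))
rra <- rraGeneScore(res, nPerm = 1000, seed = 3)
head(as.data.frame(callHits(rra, preset = "invivo")), 3)
#>      gene          rho      perm_p median_log2fc n_guides n_guides_passing_alpha   hit
#> 1 Gene001 1.554455e-13 0.000999001     0.9737025       10                     10  TRUE
#> 2 Gene028 9.457086e-03 0.032967033     0.2422719       10                      6 FALSE
#> 3 Gene051 1.657829e-02 0.039960040     0.2199780       10                      6 FALSE
```

The estimated dispersion (0.20) matches the generative value, the planted
gene ranks first with all ten guides below α and a median fold-change of
2⁰·⁹⁷ ≈ 2 (threefold effect attenuated by partial guide efficacy), and it
is the only gene passing the in vivo cut-offs. `runPipeline()` chains
simulate → profile → screen into one seeded, byte-reproducible run that
writes every table plus a JSON manifest.

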