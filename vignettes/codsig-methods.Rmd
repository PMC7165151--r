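---
title: "Deriving and applying a core diffuse-type gastric cancer signature"
author: "codsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying a core diffuse-type gastric cancer signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codsig)
```

## The problem

Diffuse-type gastric cancer is molecularly heterogeneous: a subset of
tumors carries an EMT/TGFβ-driven expression program and a markedly worse
prognosis, while another subset resembles intestinal-type disease, with
higher proliferation and DNA-damage-response activity, higher tumor
mutation burden (TMB) and enrichment of the MSI and EBV molecular
subtypes. `codsig` implements a workflow that derives a gene signature
separating these two states — the *core diffuse-type* (COD) and
*intestinal-like* (INT) subtypes — from a mixed discovery cohort, and then
uses that signature for prognosis and treatment-relevant contrasts in
independent cohorts.

## Derivation model

The derivation assumes a log2-scale, library-normalized gene × sample
matrix covering normal gastric tissue, intestinal-type and diffuse-type
tumors.

1. **Variance filter.** Genes with across-sample SD > 0.9 (sample SD,
   denominator $n-1$; strict inequality) enter clustering. The threshold is
   in log2 units; on typical bulk data it retains the most variable few
   thousand genes.
2. **Three-group clustering.** Samples are clustered agglomeratively.
   Neither a distance nor a linkage is canonical for expression heatmaps,
   so both are explicit parameters recorded in every result; the defaults
   are 1 − Pearson correlation with average linkage, the most common pairing
   in this literature. The tree is cut at $k = 3$.
3. **Cluster labelling.** The cluster richest in normal tissue is N, the
   richer in intestinal-type tumors of the remaining two is INT, the last is
   COD. Ties (possible only in degenerate cohorts) raise an error rather
   than guessing. Diffuse-type tumors landing in the N cluster are treated
   as normal-contaminated tumor tissue.
4. **Differential expression.** Per-gene Welch t tests on *diffuse-type
   samples only*, whose group memberships come from the full-cohort
   clustering: list A = N vs INT, list B = INT vs COD, each at unadjusted
   p < 0.001. The screen runs over all genes, not only the variance-filtered
   set: the filter exists to stabilize clustering, and the published list
   sizes do not pin the universe down. An optional Benjamini–Hochberg mode
   is available but off by default, matching the original unadjusted screen.
5. **Venn partition.** only-A genes track tumorigenesis shared with the
   intestinal-like state; A∩B genes separate all three groups; **only-B**
   genes — differential between INT and COD but *not* between N and INT —
   are the COD signature. Each signature gene carries a direction: +1 when
   its mean in the COD cluster exceeds its mean in the INT cluster.

The partition obeys exact set identities (|only-A| + |A∩B| = |A|, etc.);
with the published list sizes |A| = 737, |B| = 2069, |A∩B| = 147 these give
590 and 1922 — reproduced exactly by `venn_partition()` and checked in the
test suite.

## Classification of new cohorts

`classify_cohort()` z-scores each signature gene within the new cohort, so
platform-level location/scale differences (RNA-seq vs array) cancel without
explicit batch correction. Signature genes missing from the cohort are
dropped (never imputed) and the overlap fraction is reported; classification
refuses to run below a 25% overlap floor (configurable). Two methods:

- **two_cluster** (default, mirrors the derivation): cluster at $k = 2$ and
  orient by the *orientation score* — the per-sample mean of
  direction-weighted z-scores. The cluster with the higher mean score is
  COD. An exact tie is an error requiring manual orientation; the
  direction-weighted-mean rule is this package's formalization of the
  EMT-inspection step that is usually done by eye.
- **centroid**: label each sample by the sign of its own orientation score.
  This extends classification to single samples, which pure clustering
  cannot do, and agrees with two_cluster on well-separated cohorts (tested).

## Survival analysis

Kaplan–Meier estimation, log-rank tests and Cox proportional-hazards models
are computed via the `survival` package behind a uniform result container
(HR, 95% Wald CI, Wald p, log-likelihood, ties method).

- **Ties.** Efron tie-handling is the default — cohort survival is often
  recorded at month resolution, where Efron is clearly better. Breslow is
  available; with Breslow ties and a single binary covariate the Cox score
  statistic at $\beta = 0$ equals the log-rank statistic *for untied event
  times* — with ties the log-rank variance includes a finite-population
  multiplicity correction that the Breslow score omits, so the package's
  equivalence tests use continuous times.
- **Variable selection.** Backward elimination on Wald p at 0.05 by
  default, with an option to force covariates (e.g. the signature) into the
  model; "a variable selection procedure" is underspecified in this
  literature, so the choice is recorded in the output. AJCC substages
  collapse to the main stage and enter models as ordinal 1–4. Missing
  covariates are handled by complete-case analysis with dropped-row counts
  reported.
- **Treatment interaction.** `interaction_analysis()` fits a
  chemotherapy-only Cox model within each subtype stratum plus a pooled
  model with a subtype × chemotherapy product term. A stratum with no
  treated (or no untreated) patients returns `NULL` for that stratum rather
  than failing the whole analysis.

## Mutation profiling

TMB defaults to the raw count of nonsynonymous records per sample (silent
calls excluded); per-megabase normalization with a configurable exome size
(38 Mb default) is available since no normalization is canonical. The
INT-vs-COD TMB contrast uses a Welch t test on log10(TMB + 1) by default —
mutation counts are heavy-tailed and overdispersed — with a raw-scale
option. The per-gene screen builds a mutated/wild-type × INT/COD table per
gene and applies the two-sided Fisher exact test (point-probability
definition, the dominant convention, rather than doubling one tail),
unadjusted at α = 0.05 with a BH column emitted alongside. The molecular
subtype association is a Pearson χ² test on the class × subtype table.

## The synthetic cohort generator

`simulate_cohort()` generates the latent structure the analysis assumes,
from one seed, in a documented draw order (modules, sample labels,
expression, covariates, survival, mutations), so identical configurations
are bit-identical.

- **Expression**: per-gene baseline ~ N(6, 1); an INT module (default 252
  genes) up-shifted by `effect_size` in intestinal-type and INT-like
  diffuse samples; a COD module (default 397 genes) up-shifted in COD-like
  diffuse samples; i.i.d. Gaussian noise with SD `noise_sd`. N-like diffuse
  tumors are a 0.9 : 0.1 mixture of the normal and COD profiles — dominated
  by normal stomach patterns, as their discovery-cohort counterparts are.
- **Sample counts** default to the 150-sample discovery design (20 normal,
  23 intestinal-type, 107 diffuse-type), with diffuse samples split
  15/35/50% into N-like/INT-like/COD-like — proportions consistent with the
  reported cluster compositions.
- **Survival**: exponential by default (a Weibull shape is exposed), with
  hazard = `baseline_hazard` × 2.0^[COD] × per-subtype chemotherapy HR
  (0.333 in COD, 0.576 in INT) for treated patients, independent
  exponential censoring and an optional administrative horizon. The
  exponential default makes proportional hazards exact, so hazard-ratio
  recovery has a clean truth. `baseline_hazard` = 0.01/month and
  `censor_rate` = 0.006/month give a median survival of several years and
  roughly 30% censoring, typical of resected gastric cancer cohorts.
  Optional stage and age hazard effects default to off, so the marginal and
  conditional subtype HR coincide in recovery experiments.
- **Mutations**: per-sample negative-binomial background counts
  (means 8 INT-like vs 2 COD-like, dispersion 2 — overdispersed, so TMB
  t tests face realistic heavy tails) spread uniformly over genes, plus
  designated marker loci drawn at per-subtype frequencies: a MUC16-like
  locus (0.15 INT / 0.42 COD, giving a ~31% overall diffuse-cohort rate)
  and PIK3CA/ARID1A-like loci enriched in INT.

Effect sizes and noise levels for real cohorts are unknown; the defaults
(`effect_size` 1, `noise_sd` 1) are deliberately arbitrary and documented as
such. Recovery experiments use effect 2 / noise 0.5, a clearly separable
regime: they validate the machinery, not field performance. The generator
omits batch effects, library-size artifacts, read-count noise,
copy-number/methylation structure and EBV biology — passing recovery tests
therefore demonstrates correctness of the pipeline under its own model, not
expected accuracy on clinical data.

## Numerical choices and degenerate inputs

- Expression matrices must be finite: missing entries are rejected at load
  unless per-gene median imputation is explicitly requested. Duplicate gene
  rows collapse to the row with the highest mean expression (or the mean,
  configurable).
- Welch t with zero variance in both groups: p = 1 for equal means,
  p = 0 otherwise (separated constants).
- Fisher odds ratios add 0.5 to all cells only when a cell is zero, and
  flag it.
- Samples constant across the clustering genes make correlation distance
  undefined and are reported by name rather than silently dropped.
- Agglomeration determinism relies on `stats::hclust`'s deterministic
  merge order; determinism and permutation-invariance are tested
  properties.
- All validation suites run at fixed problem sizes chosen to make
  Monte-Carlo bands tight (e.g. 100 cohorts of n = 400 for HR recovery,
  500 replicates of n = 115 for the interaction design, 10,000 null genes
  for screen calibration); exact-test calibration is checked at n = 200 per
  arm because Fisher's exact test is conservative on small discrete tables
  and only approaches nominal α asymptotically.

## Known limitations

- The signature derivation is sensitive to the clustering parameters in
  low-separation regimes; results record the parameters used, but no
  consensus-clustering stability analysis is included.
- The centroid classifier's threshold at 0 assumes the cohort is roughly
  balanced after z-scoring; strongly skewed cohorts may need the clustering
  method.
- No time-varying covariates, competing risks or frailty terms in the
  survival suite; no variant calling or driver annotation in the mutation
  suite; no functional-enrichment analysis.
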