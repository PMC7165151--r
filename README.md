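# codsig

Diffuse-type gastric cancer (Lauren classification) is clinically
heterogeneous and carries a poor prognosis, yet has few reliable molecular
markers. `codsig` implements a cluster-derived gene-signature workflow that
splits diffuse-type tumors into two molecular subtypes with different
outcomes and treatment implications:

- **INT** (intestinal-like): proliferation/DNA-repair-high, higher tumor
  mutation burden, enriched for MSI/EBV molecular subtypes;
- **COD** (core diffuse-type): EMT/TGFβ-high, poor prognosis, but with a
  larger benefit from adjuvant chemotherapy.

The package is aimed at translational cancer researchers working with bulk
expression cohorts (log2-scale gene × sample matrices), per-sample clinical
tables and MAF-lite mutation tables.

## The method

**Derivation.** On a discovery cohort containing normal, intestinal-type and
diffuse-type samples:

1. keep genes with across-sample SD > 0.9 (log2 units);
2. agglomeratively cluster samples (1 − Pearson correlation, average
   linkage) and cut at k = 3;
3. label the clusters N / INT / COD by histological composition;
4. on diffuse-type samples only, screen genes by per-gene Welch t tests at
   p < 0.001 for two contrasts: N vs INT (list *A*) and INT vs COD
   (list *B*);
5. partition: only-A = A \\ B, A∩B, only-B = B \\ A. The **COD signature**
   is the only-B set — genes tracking progression into the COD state rather
   than tumorigenesis per se — with a per-gene direction
   (+1 if higher in COD).

**Application.** A new cohort is z-scored per signature gene, clustered at
k = 2 (or scored per sample against the signature centroid), and the cluster
with the higher direction-weighted mean is called COD. Downstream analyses:
Kaplan–Meier / log-rank and Cox proportional-hazards models
(HR = exp(β), 95% Wald CI), backward variable selection, a
chemotherapy × subtype interaction model, TMB contrasts (Welch t on
log10(TMB+1)), per-gene Fisher exact mutation screens, and a χ² association
test against TCGA molecular subtypes (EBV/MSI/GS/CIN).

A synthetic-cohort generator (`simulate_cohort()`) produces expression,
clinical and mutation data with this exact latent structure — known gene
modules, a configurable COD-vs-INT hazard ratio (default 2.0), per-subtype
chemotherapy hazard ratios (defaults 0.333 / 0.576) and subtype-dependent
mutation burden — so every stage can be validated against ground truth.

## Worked example

```r
library(codsig)

cfg    <- simulation_config(effect_size = 2, noise_sd = 0.5, seed = 7)
cohort <- simulate_cohort(cfg)          # 150 samples x 2000 genes
sig    <- derive_signature(cohort$expression, cohort$clinical)
print(sig)
#> <cod_signature> 391 genes (only-B), SD > 0.9 filter kept 649 genes, DE p < 0.001
#> <gene_list_partition> |A| = 259, |B| = 650: only-A 0, A-and-B 259, only-B 391

# classify an independent cohort and test prognosis
fresh    <- simulate_cohort(simulation_config(effect_size = 2, noise_sd = 0.5, seed = 8))
d_ids    <- fresh$clinical$sample_id[fresh$clinical$histology == "diffuse"]
subtypes <- classify_cohort(expression_matrix(unclass(fresh$expression)[, d_ids]), sig)
table(subtypes$subtype)
#> COD INT
#>  54  53

clin <- fresh$clinical[match(subtypes$sample_id, fresh$clinical$sample_id), ]
logrank_test(clin$os_time, clin$os_event, subtypes$subtype)
#> log-rank test: statistic = 4.348, df = 1, p = 0.03706

cox_fit(data.frame(subtype_cod = as.numeric(subtypes$subtype == "COD"),
                   age = clin$age, stage = as.numeric(clin$ajcc_stage)),
        clin$os_time, clin$os_event)
#> Cox proportional hazards (efron ties), n = 107, events = 67
#>         term        coef         se              hr_ci    p_value
#>  subtype_cod  0.57196599 0.25406272   1.77 (1.08-2.92) 0.02436789
#>          age  0.01629616 0.01380437  1.02 (0.989-1.04) 0.23779840
#>        stage -0.18526925 0.15118648 0.831 (0.618-1.12) 0.22041125

ia <- interaction_analysis(subtypes$subtype, clin$chemo, clin$os_time, clin$os_event)
#> chemo HR within COD: 0.255 (p = 0.001)
#> chemo HR within INT: 0.431 (p = 0.047)
```

The signature recovers the planted COD module (391 of 397 genes here), the
classified subtypes separate survival (log-rank p = 0.037; adjusted subtype
HR 1.77 at n = 107), and the simulated chemotherapy benefit concentrates in
the COD stratum — the qualitative behavior the signature is designed to
expose.

An end-to-end run (simulate → derive → classify → survival → mutations)
with one seed:

```r
run_all(list(simulate = TRUE, seed = 1, out_dir = "out"))
# writes out/report.json, out/report.md, out/signature.json, out/subtypes.tsv
```

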