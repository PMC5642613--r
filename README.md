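# coexsurv

Co-expression module discovery and survival stratification for tumor
cohorts, built around the question of whether B-cell / immunoglobulin
activity in the tumor microenvironment predicts outcome in hepatocellular
carcinoma (HCC).

## What it does

The package implements a three-stage analysis as a tested, reusable
pipeline:

1. **Module discovery.** On a gene-by-sample log-expression matrix
   (multi-entity, pan-cancer), genes are Z-scored per array, screened for
   co-expression (`|CC| > 0.8` to at least one partner, CC = Pearson
   correlation), transformed to the distance `d = 1 − |CC|`, clustered by
   complete linkage, and partitioned at a cluster count *k* selected by
   the Krzanowski–Lai index (maximized),

   KL(k) = |DIFF(k) / DIFF(k+1)|,  DIFF(k) = (k−1)^(2/p)·W(k−1) − k^(2/p)·W(k),

   and the Hubert–Levin C index (minimized),
   C = (S − S_min)/(S_max − S_min). Modules are reported with their
   within-module CC range.
2. **Cohort validation.** A module is projected onto an independent
   cohort with paired tumor/non-tumor arrays from two platforms: quantile
   normalization over the platforms, reduction to the module gene
   cut-set, gene-then-array standardization, complete-linkage grouping of
   tumor arrays into high/low module-expression groups, then
   Kaplan–Meier curves, the log-rank test, and a Cox proportional-hazards
   ratio HR = hazard(low)/hazard(high) with Efron ties and Wald 95% CI.
3. **Region-stratified IHC statistics.** B-cell counts per high-power
   field (markers CD20, CD79a) in tumor (Tu), infiltrative margin (Im)
   and distant stroma (Sd) regions: mean ± SEM, Mann–Whitney region
   comparisons, mean-split high/low dichotomization with log-rank
   survival comparison, Pearson cross-correlations, and exact-test
   associations with Kappa/IgM positivity and clinical covariates.

Because the original cohorts are external, a synthetic-data module
generates all three (planted co-expression modules, a configurable true
hazard ratio, overdispersed count distributions matched to configured
mean ± SEM) with ground-truth tables, so every estimator in the pipeline
is calibrated against known truth. The shipped default configurations
(`inst/extdata/*.yaml`) mirror the cohort statistics the pipeline is
designed around: a 42-gene module, a 242-patient validation cohort with
true HR 1.5, and a 119-patient IHC cohort with region means such as
65 ± 5 CD20⁺ cells/HPF at the infiltrative margin.

See the methods vignette
(`vignettes/coexpression-survival-methods.Rmd`) for the full model
description, parameter meanings and design choices.

## Worked example

```r
library(coexsurv)

## 1. discover the planted module on a synthetic pan-cancer cohort
em <- generate_pancancer_cohort(seed = 3)
disc <- discover_modules(em)
print(disc$validity)
print(disc$modules)

## 2. project it onto the validation cohort and stratify survival
vc <- generate_validation_cohort(seed = 3)
val <- validate_module_survival(vc$expression,
                                disc$modules$modules$module_1,
                                vc$survival)
print(val$hr)
cat("log-rank p:", signif(val$logrank$p, 3), "\n")

## 3. region-stratified IHC analysis
ihc <- generate_ihc_cohort(seed = 3)
rep <- ihc_region_analysis(ihc$counts, ihc$survival)
print(rep$markers$CD20$region_summary)
cat("CD20 Im log-rank p:",
    signif(rep$markers$CD20$survival_by_region$Im$logrank_p, 3), "\n")
```

Output:

```
63 of 563 genes pass |CC| > 0.8
Cluster-count validity profile (k in 2..10)
KL index selects k = 2 ; C index selects k = 2
selected: 2 (by KL)
ModuleSet with 2 modules
    module size    cc_min    cc_max
1 module_1   42 0.8466680 0.9033617
2 module_2   21 0.8236946 0.8779340
42 of 42 module genes present
HR 1.51 (95%CI 1.09-2.09), low vs others, efron ties, p = 0.01317
log-rank p: 0.0125
  region      mean      sem   n
1     Tu  7.291317 1.347105 119
2     Im 66.266106 4.526679 119
3     Sd 23.417367 2.682327 119
CD20 Im log-rank p: 0.0012
```

Reading this: the correlation screen keeps exactly the 63 planted module
genes; both validity indices agree on k = 2 and the largest module is the
full 42-gene planted analogue with within-module CC 0.85–0.90. Projected
onto the validation cohort, the cluster-derived low-expression group has
1.51× the hazard of the high group (the configured truth is 1.5), with
the log-rank test rejecting at p ≈ 0.013. In the IHC cohort the margin
(Im) carries by far the highest B-cell density (66 ± 5 vs 7 ± 1 and
23 ± 3 cells/HPF), and Im-high patients survive significantly longer
(p ≈ 0.001), reflecting the generator's protective margin-infiltration
link.

A thin command-line wrapper with `simulate`, `discover`, `validate` and
`ihc` subcommands lives at `inst/cli/coexsurv.R`; all subcommands take
`--seed`, `--out-dir` and an optional YAML `--config` overriding the
shipped defaults.

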