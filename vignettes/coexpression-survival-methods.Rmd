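---
title: "Methods: co-expression module discovery, survival stratification and region-stratified B-cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression module discovery, survival stratification and region-stratified B-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

`coexsurv` implements a three-stage analysis linking an immunoglobulin-like
gene co-expression module and B-cell infiltration to survival in
hepatocellular carcinoma (HCC):

1. **Module discovery.** On a pan-cancer, multi-entity expression matrix,
   genes are screened for strong co-expression, clustered on a
   correlation-derived distance, and partitioned into modules at a cluster
   count chosen by internal validity indices.
2. **Cohort validation.** A discovered module is projected onto an
   independent cohort with paired tumor/non-tumor arrays from two
   platforms; arrays are grouped into high/low module-expression groups and
   the groups are compared by Kaplan–Meier curves, the log-rank test and a
   Cox hazard ratio.
3. **Region-stratified immunohistochemistry.** In a surgical resection
   cohort, B cells (CD20⁺, CD79a⁺) are counted per high-power field (HPF)
   in three regions — tumor (Tu), infiltrative margin (Im), distant stroma
   (Sd) — and the counts drive mean ± SEM summaries, region comparisons,
   mean-split survival stratification, and associations with
   immunoglobulin (Kappa light chain, IgM) positivity and clinical
   covariates.

Because the original cohorts are external, a synthetic-data module
generates all three cohorts with known ground truth, so that every stage is
exercised — and its estimators calibrated — without any download.

# Stage 1: module discovery

The discovery matrix holds log-scale expression, genes in rows and arrays
in columns; the loader performs no transformation (summarization and
per-platform preprocessing are assumed done upstream, and probe-level rows
can be collapsed to genes by per-array averaging over an annotation map).

The chain is:

* **Per-array Z-score** (`zscore_by_array`): every column is centred and
  scaled to sample (n−1) standard deviation 1. The sample convention is
  used throughout the package; it is the default of the statistical
  software this field uses, and at the sizes involved the population/sample
  distinction is immaterial.
* **Correlation screen** (`pairwise_correlation`,
  `filter_correlated_genes`): Pearson correlation between all gene pairs;
  genes with at least one *other* gene at `|CC| > 0.8` (strict) are
  retained. The screen is per-gene-best-partner, not per-pair, so a
  retained module may legitimately contain pairs below the threshold —
  which is why a module's internal correlation range can reach well below
  0.8.
* **Distance and clustering** (`correlation_distance`,
  `hierarchical_cluster`): `d = 1 − |CC|`, complete-linkage agglomeration.
  The absolute value treats strong negative co-regulation as proximity;
  complete linkage keeps modules compact.
* **Cluster count** (`select_cluster_count`): two standard internal
  indices are computed for each candidate `k`:
  * Krzanowski–Lai: `KL(k) = |DIFF(k) / DIFF(k+1)|` with
    `DIFF(k) = (k−1)^{2/p} W_{k−1} − k^{2/p} W_k`, where `W_k` is the total
    within-cluster sum of squared deviations from cluster centroids with
    genes as points and the `p` arrays as feature dimensions; maximized.
  * Hubert–Levin C: `C = (S − S_min) / (S_max − S_min)`, with `S` the sum
    of within-cluster pairwise distances and `S_min`/`S_max` the sums of
    the same number of smallest/largest distances overall; minimized.

  `W_k` is deliberately computed in the expression space rather than on
  the `1 − |CC|` distances: the KL index is defined on feature-space
  dispersion, and the `k^{2/p}` exponent only makes sense with `p` equal
  to the feature dimension. The clustering distance is used for tree
  building and for the C index. When the two indices disagree the profile
  reports both and the pipeline takes an explicit choice
  (`select_by`, default `"KL"`). `KL(k)` is flagged undefined (and
  excluded from the argmax) when `DIFF(k+1) = 0`; the C index is an error
  when all pairwise distances are equal.
* **Extraction** (`extract_modules`): the tree is cut at the selected `k`;
  modules are indexed by decreasing size and annotated with their
  within-module correlation range. `module_stability_in_subset` recomputes
  within-module correlations on a single entity's samples (e.g. the
  HCC-like entity) to ask whether a pan-cancer module stays coherent
  there.

Agglomeration ties are resolved by `stats::hclust`'s deterministic
ordering; on the continuous distances this pipeline produces, exact ties
have probability zero, and the test suite checks equivalence with a
brute-force agglomerative oracle on small instances.

# Stage 2: cohort validation

The validation cohort carries paired tumor/non-tumor arrays from two
platforms. The chain follows the discovery conventions:

1. **Quantile normalization over both platforms**
   (`quantile_normalize`): every array is mapped onto the mean sorted
   profile; ties receive the mean reference value of their occupied ranks
   (the limma convention, which is deterministic). The transform is
   idempotent, which the suite asserts.
2. **Projection** (`project_module`): the matrix is reduced to the cut-set
   of module genes present in the cohort; misses are counted and
   reported, mirroring the situation where only part of a discovery
   module is represented (or retains co-regulation) in an independent
   cohort.
3. **Double standardization** (`double_standardize`): genes are centred
   and scaled, then arrays are centred and scaled. Only the second
   (array) contract survives on the output — the pass order necessarily
   breaks the first — and only the column contract is asserted. One
   consequence worth knowing: an expression shift common to *all*
   projected genes of an array is exactly absorbed by the array-wise
   centring. Group structure therefore survives this standardization only
   when it is a contrast *within* the projected gene set, which is the
   case when a proper subset of module genes carries the signal.
4. **Array grouping** (`group_arrays`): complete-linkage clustering of
   tumor arrays on Euclidean distance over the standardized module genes,
   cut at `k = 2`. Two groups are used because the downstream survival
   comparison is binary (high vs low module expression); the cluster with
   the larger mean module expression on the pre-standardization scale is
   labelled `high`. Significance of per-gene tumor vs non-tumor
   differences is reported (Welch t, rank-sum, linear-scale fold change
   and its log2) but does not gate the grouping.
5. **Survival stratification**: Kaplan–Meier curves per group, the
   log-rank test, and a Cox proportional-hazards hazard ratio with Efron
   tie handling (Breslow behind a flag) and a Wald 95% CI on the log
   scale. The reported HR is hazard(low)/hazard(high), so values above 1
   mean low module expression carries the higher hazard; this matches the
   convention in which the high-expression group survives longer with an
   HR of about 1.5.

Fold changes are computed on the unlogged scale (`mean(2^x_tumor) /
mean(2^x_non_tumor)`), with `logFC = log2(FC)`, so that listing "fold
change and log fold change" as separate descriptors is meaningful; no
multiple-testing correction is applied to the per-gene descriptors, an
omission inherited from the analysis design and left to the caller.

# Stage 3: region-stratified IHC statistics

`ihc_region_analysis` consumes per-patient, per-marker, per-region triples
of field counts (three randomly selected 20× fields; their mean is the
patient's value) and produces:

* per-region mean ± SEM (`SEM = sd/√n`);
* pairwise region comparisons (Im vs Tu, Im vs Sd, Tu vs Sd) by the
  Mann–Whitney test. The test is exact (full enumeration) when the data
  are tie-free and `n_a·n_b ≤ 400`, otherwise a normal approximation with
  tie and continuity correction. Regions are paired within patients, and
  a Wilcoxon signed-rank alternative is available behind `paired = TRUE`,
  but the unpaired test is the default to match the declared analysis;
* per-region mean-split dichotomization (`split_high_low`: strictly above
  the cohort mean → `high`; equal-to-mean values go to `low`, a boundary
  the analysis never had to define and which is fixed here conservatively)
  followed by a log-rank comparison of the two groups;
* cross-marker and cross-region Pearson correlations of the per-patient
  means;
* 2×2 exact (Fisher) tests of the Im high/low status against binary
  clinical covariates, and Kappa/IgM positivity fractions per region
  compared between Im-high and Im-low patients. The exact test is the
  package's choice — no categorical test was named in the original
  design.

Patients missing any region of a marker are excluded from that marker's
analysis with a reported count; nothing is imputed.

# The synthetic cohorts

The generators define the study conditions; their defaults ship as YAML
under `inst/extdata/` and every stage's calibration is run against them.

**Pan-cancer discovery cohort** (`generate_pancancer_cohort`): 300 samples
over six entities (an HCC-like entity of 45 samples among them), 500
background genes, and planted modules driven by one shared latent factor
each with equal loadings: `gene = mu + noise·(√cc·f + √(1−cc)·eps)`, so
the expected pairwise correlation is exactly `cc` — the simplest
construction with an analytically known target. The default plants the
42-gene module of interest at `cc = 0.9` plus a 21-gene companion module
at `cc = 0.85`. The companion is a design necessity, not decoration: after
the `|CC| > 0.8` screen only co-regulated genes survive, and a
cluster-count search over `k ≥ 2` cannot return a single undivided module;
with two planted modules the true `k = 2` is well-posed and the largest
extracted module is the 42-gene analogue. Background genes are
independent, so at 300 samples no background pair approaches the 0.8
screen.

**Validation cohort** (`generate_validation_cohort`): 242 patients, paired
tumor/non-tumor arrays, two platforms with location/scale offsets (removed
downstream by quantile normalization). Ten of the 42 module genes remain
co-regulated in tumor tissue (a shared per-patient factor) and carry a
log2 overexpression shift of 1.5 in a random half of the cohort; survival
is exponential with hazard(low) = `baseline · true_hr` (default 1.5, the
headline effect size), hazard(high) = `baseline = 0.012`/month,
administratively censored at 60 months — with proportional hazards exact
by construction, hazard-ratio recovery is a clean estimator test. The
truth tables (per-patient group, per-gene role) score every recovery
claim.

**IHC cohort** (`generate_ihc_cohort`): 119 patients; per marker and
region, a patient-level latent intensity is drawn from a gamma (negative
binomial default) or lognormal distribution and three Poisson field
counts are drawn around it. The latent variance is set to
`(SEM·√119)² − mean/3`, so the per-patient mean of the three counts has
exactly the dispersion implied by the configured mean ± SEM (CD20:
8 ± 2 / 65 ± 5 / 25 ± 3 cells/HPF for Tu/Im/Sd; CD79a: 13 ± 3 / 62 ± 7 /
23 ± 3). These dispersions are strongly overdispersed relative to Poisson
(e.g. Im CD20 per-patient sd ≈ 5·√119 ≈ 54.5 against mean 65), which is
why the negative binomial is the default; the lognormal variant exists for
configurations with sub-Poisson overdispersion, where the gamma mixture is
infeasible and the generator refuses with a pointer to the alternative.
Only mean ± SEM was ever stated for these counts, so the family choice is
a modelling decision, flagged as such. Survival is tied to the CD20
Im-region mean split (hazard ratio 0.45 for Im-high, baseline
0.0147/month ≈ a 47-month median in the low group, censoring at 120
months), matching the direction and approximate strength of the observed
margin effect; Kappa/IgM positivity and a cirrhosis covariate are
Bernoulli-linked to the same status.

What the generators deliberately do **not** emulate: probe-level noise,
batch effects beyond the two-platform offsets, non-proportional hazards,
informative censoring, correlated field counts beyond the shared latent
intensity, and any real biological annotation of gene ids. Passing tests
therefore demonstrate that the pipeline's estimators recover known
structure under clean conditions — not that the original cohorts would
reproduce, which would require the external data.

# Numerical choices and degenerate inputs

* Sample (n−1) standard deviation everywhere.
* Loaders reject rather than repair: duplicate ids, non-numeric or missing
  cells, negative times/counts, unknown regions or event codes are errors
  naming the offending record (a region label outside Tu/Im/Sd — e.g. the
  occasional "Sn" typo — is refused, not remapped).
* Zero-variance genes/arrays are errors at the pass where they arise, with
  the offender named.
* `KL` undefined at a `k` (zero denominator) excludes that `k`; an
  all-identical input makes the C index undefined and is an error.
* Mean-split on constant values is an error (no split exists); a group
  with no events is a monotone-likelihood error in the Cox fit, not a
  silently huge HR.
* Problem sizes used by the shipped calibration: 50 seeds for module
  recovery (563 genes × 300 samples each), 200 replicates for
  hazard-ratio recovery and CI coverage at n = 242, 500 replicates for
  log-rank type-I error at n = 60/60, 50 replicates for IHC moment
  recovery at n = 119. These sizes give Monte-Carlo standard errors a
  small fraction of the tolerances checked against.

# Known limitations

* With a single retained gene subset the array grouping is
  unsupervised k = 2 complete linkage; when the true subgroups are far
  from balanced or the effect is weak, the cut can track noise — the
  hazard-ratio calibration therefore evaluates the Cox stage on true
  labels, and group-recovery is assessed separately at strong effect.
* The mean-split dichotomization discards within-group dose information;
  it is kept because it is the design under study.
* The pipeline reports per-gene descriptors without multiplicity
  correction, as in the design it follows.
* Survival endpoints are whatever the input encodes; overall vs
  recurrence-free survival are not distinguished.
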