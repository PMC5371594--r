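# mklpet

Region-kernel support vector classification of dopaminergic PET brain
volumes.

`mklpet` is for neuroimaging methodologists who want to separate
idiopathic Parkinson's disease (PD) from the atypical parkinsonian
syndromes — multiple system atrophy (MSA) and progressive supranuclear
palsy (PSP) — on striatal PET-like volumes (e.g. ^18^F-DMFP), and to
evaluate such classifiers rigorously without access to clinical data.
It provides the full chain: NIfTI volume handling, a synthetic phantom
cohort generator, affine spatial normalization against a symmetric
template, top-intensity normalization, atlas parcellation, a
multiple-kernel-learning (MKL) SVM, data-driven region selection, and
an evaluation harness with nested cross-validation, permutation
significance testing, ROC analysis and voxelwise t-maps.

## The method

A soft-margin SVM is trained in the dual,

    max_α  Σ αᵢ − ½ Σᵢⱼ αᵢαⱼ yᵢyⱼ k(xᵢ,xⱼ)   s.t.  0 ≤ αᵢ ≤ C,  Σ αᵢyᵢ = 0,

over a convex combination of per-region linear kernels

    k(xᵢ,xⱼ) = Σₘ qₘ kₘ(xᵢ⁽ᵐ⁾, xⱼ⁽ᵐ⁾),   qₘ ≥ 0,  Σ qₘ = 1,

so regions with small absolute uptake (olfactory region, thalamus,
supplementary motor area) can contribute alongside the dominant
striatum. Regions are selected per training fold from the mean absolute
primal weight w = Σ αᵢyᵢxᵢ of a whole-brain linear SVM (top 5 by
default); (C, q) are tuned by an inner 5-fold grid search over
C = 2^e, e ∈ {−3,…,5} and all simplex-lattice weight vectors with step
0.1. Binary mode pools MSA∪PSP as the positive class; multiclass mode
uses a one-against-one ensemble; multimodal mode appends a DaTSCAN
striatum kernel.

## Worked example

Clinical cohorts for this problem are not publicly deposited, so the
package ships a phantom generator whose defaults emulate the study
design it models: three groups with reduced atypical striatal/thalamic
binding and reduced idiopathic olfactory/supplementary-motor uptake.

```r
library(mklpet)
spec   <- phantom_spec()
atl    <- make_toy_atlas(spec)
cohort <- simulate_cohort(spec, c(PD = 15, MSA = 8, PSP = 7), seed = 1)
report <- run_cv_pipeline(cohort, atl, merge_config(list(k = 5, seed = 1)))
report
#> <cv_report> mode=binary, k=5, accuracy 100.00%
#>   sensitivity 100.00%, specificity 100.00%
report$folds[[1]]$regions
#> [1] "putamen" "caudate" "olfactory" "thalamus" "supplementary-motor-area"
roc_curve(report$decision, report$truth, "atypical")$auc
#> [1] 1
```

Accuracy is the pooled out-of-fold correct rate; sensitivity is the
true-positive rate of the pooled atypical (MSA+PSP) class and
specificity the true-negative rate of the PD class. Each fold's record
also logs the selected regions and tuned (C, q) — here the selection
recovers exactly the five effect-carrying regions, and on this
strong-effect phantom the separation is perfect (clinical data would
not be; published rates for the real problem are near 70%).
Significance comes from a permutation test that re-runs the whole
pipeline (selection included) under relabelings:

```r
cache <- attr(report, "cache")
cfg_p <- merge_config(list(k = 5, top_k = 2, C_exponents = 0,
                           q_step = 0.5, seed = 1))
permutation_test(function(lab) run_cv_features(cache, lab, cfg_p)$accuracy,
                 cache$labels, n_perm = 99, seed = 2)
#> <permutation_result> observed 1.0000, p = 0 (99 permutations)
```

A command-line front end wraps the same functions
(`inst/cli/mklpet`): `simulate`, `preprocess`, `features`, `train`,
`evaluate`, `permtest`, `ttest`, `roc`, all driven by one YAML config.

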