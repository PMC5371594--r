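---
title: "Region-kernel SVM classification of dopaminergic PET volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-kernel SVM classification of dopaminergic PET volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Differentiating idiopathic Parkinson's disease (PD) from the atypical
parkinsonian syndromes — multiple system atrophy (MSA) and progressive
supranuclear palsy (PSP) — is difficult early in the disease, when
symptoms overlap. Imaging of post-synaptic dopamine D2/3 receptors
(e.g. with the PET radioligand ^18^F-DMFP) concentrates most of its
signal in the striatum, but carries usable extrastriatal signal too.
`mklpet` implements a multivariate analysis that exploits exactly this:
a support vector machine over a weighted combination of per-region
kernels, so that small regions with low absolute uptake (olfactory
region, thalamus, supplementary motor area) can contribute to the
decision alongside the dominant striatal signal instead of being
drowned by it.

## The model

A binary soft-margin SVM separates the two groups with the decision
function $g(x) = w^\top x + w_0$. Training solves, in the dual,

$$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j
y_i y_j\, k(x_i, x_j), \qquad 0 \le \alpha_i \le C, \quad
\textstyle\sum_i \alpha_i y_i = 0,$$

where $C$ trades margin width against training error and $k$ is the
kernel. For region-based classification the kernel is a convex
combination of per-region linear kernels

$$k(x_i, x_j) = \sum_{m=1}^{N_k} q_m\, k_m(x_i^{(m)}, x_j^{(m)}),
\qquad q_m \ge 0,\ \sum_m q_m = 1,$$

with $x^{(m)}$ the voxel intensities of region $m$. The weights $q_m$
absorb the scale differences between regions (striatal features are an
order of magnitude larger than extrastriatal ones), acting as a
regularizer that assigns one weight per region rather than one per
voxel.

Regions are not fixed a priori. A whole-brain linear SVM is trained
first; its primal weight vector $w = \sum_i \alpha_i y_i x_i$ assigns
an importance to every voxel, and each region's importance is the mean
of $|w|$ over its voxels. The top-$k$ regions (default $k = 5$) enter
the multi-kernel classifier. On phantoms with seeded effects this
recovers putamen, caudate, olfactory region, thalamus and supplementary
motor area fold after fold.

## The evaluation harness

`run_cv_pipeline()` reproduces the full protocol: stratified 10-fold
cross-validation where *within each training fold* (a) the whole-brain
SVM is trained, (b) region importances are computed and the top five
regions selected, (c) $(C, q)$ are tuned by an inner 5-fold grid search
over $C = 2^e$, $e \in \{-3, \dots, 5\}$ and all lattice weight vectors
with entries in $\{0.1, \dots, 0.9\}$ summing to 1 (126 vectors for five
kernels), and (d) the MKL model is trained and applied to the held-out
fold. Pooled out-of-fold predictions yield accuracy, sensitivity and
specificity; the positive class is the pooled non-idiopathic group
(MSA $\cup$ PSP). Three-group classification uses a one-against-one
ensemble with majority voting, reporting per-class accuracies.
Significance of the cross-validated accuracy is assessed by a
permutation test: the complete pipeline — including region selection —
is re-run under random relabelings and the p-value is the fraction of
permuted runs with accuracy at least the observed one.

```{r example}
library(mklpet)
spec <- phantom_spec()
atl <- make_toy_atlas(spec)
cohort <- simulate_cohort(spec, c(PD = 30, MSA = 15, PSP = 15), seed = 1)
report <- run_cv_pipeline(cohort, atl, merge_config(list(seed = 1)))
report
```

## The phantom generator

Clinical DMFP/DaTSCAN volumes are not publicly deposited, so every
stage is exercised on synthetic cohorts. The default `phantom_spec()`
emulates the structure of the study being modelled:

* a 40×48×34 grid of 2 mm voxels (a half-resolution analogue of the
  79×95×68 template grid), with an ellipsoidal brain of baseline
  tissue uptake;
* spherical regions for bilateral putamen and caudate (baseline ~10×
  the extrastriatal tissue, mirroring the striatal dominance of
  dopaminergic tracers), thalamus, olfactory region and supplementary
  motor area at low baselines, plus four uninformative filler regions;
* multiplicative group effects on regional uptake: the atypical groups
  carry reduced striatal and thalamic binding (factors 0.65–0.8), the
  idiopathic group reduced olfactory (0.65) and supplementary-motor
  (0.80) uptake. The supplementary motor area is deliberately the
  weakest marker. Fillers are unaffected;
* i.i.d. Gaussian voxel noise (sd 1, on the scale of the tissue
  baseline) added inside the brain *before* 6 mm FWHM smoothing, so the
  final images carry spatially correlated noise;
* a three-group cohort of 39/24/24 subjects by default, with
  per-subject seeds derived from one master seed (cohorts are pure
  functions of `(spec, seed)`);
* a `datscan` modality generated by the same machinery with near-zero
  extrastriatal baseline, for the multimodal mode that appends a
  DaTSCAN striatum kernel to the five DMFP region kernels.

The phantom emulates *preprocessed* data: volumes are already on a
common grid and intensity-normalized, so the per-subject global uptake
factor defaults to 0 (`subject_scale_sd` switches it on when the
preprocessing operators themselves are under test). What the phantom
does **not** model: PET physics (attenuation, scatter, scanner PSF),
anatomical variability beyond affine misalignment, partial-volume
effects, or realistic inter-subject covariance. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery
at the stated effect sizes — not clinical-level accuracy on real data,
where published rates for this problem sit near 70%. The strong-effect
defaults produce near-perfect phantom separation by design; the null
configuration (all effect factors 1) is used to verify that the
permutation test holds its nominal type-I error.

## Preprocessing

Spatial normalization uses a plain 12-parameter affine model
(translations, rotations, scales, shears; serialized in the order
`tx ty tz rx ry rz sx sy sz hxy hxz hyz`) fitted by minimizing the mean
squared intensity difference with Nelder-Mead over a coarse-to-fine
schedule: volumes smoothed at 8/4/0 mm FWHM and decimated 4×/2×/1×,
with degrees of freedom growing 3 → 6 → 9 → 12. This deliberately
replaces the Bayesian zoom/shear prior of SPM-style registration, whose
hyperparameters are not published; the testable contract is that the
transform minimizes the similarity cost, recovers known perturbations
within half a voxel, and never returns something worse than the
identity (it falls back to the identity with a warning). Resampling is
trilinear with zero fill outside the source grid.

Templates are built by registering the volumes of the (more
homogeneous) idiopathic group to an explicitly chosen reference,
averaging them together with their hemisphere midplane reflections, and
smoothing at 8 mm; a final symmetrization makes left-right symmetry
exact rather than approximate. The reference is an explicit index, not
a random draw, so template construction is reproducible.

Intensity normalization divides each volume by the mean of its top
0.1% intensities. The voxel population defaults to a brain mask
(threshold at 10% of the maximum of the cohort mean image) rather than
the whole field of view, so air voxels never dilute the reference; the
count is `ceiling(0.001 * N)`, never less than one voxel. The operation
is exactly scale-invariant and leaves the mean of the top set at
exactly 1.

## Numerical choices

* **Dual solver.** Sequential minimal optimization over the
  precomputed kernel with second-order working-set selection,
  terminating at a KKT violation gap below 1e-8 (iteration cap
  2e5). The bias is the mean of $y_i - \sum_j \alpha_j y_j K_{ji}$
  over free support vectors, or the midpoint of the feasible interval
  when none is free. Correctness is contracted through the KKT
  conditions (tolerance 1e-4) and agreement of the dual objective with
  an independent interior-point QP solve (1e-6).
* **Kernels.** Square kernels are validated symmetric to 1e-8
  (relative) and symmetrized; positive-semidefiniteness checking with
  diagonal ridge regularization is available but off by default, since
  linear kernels are PSD by construction.
* **Ties.** `sign(0)` maps to the positive class; region-importance
  ties break alphabetically; grid-search ties prefer the smaller $C$,
  then the lexicographically smallest $q$; one-against-one vote ties
  fall to the largest summed decision magnitude, then alphabetically.
  All ties are therefore deterministic.
* **Smoothing.** Separable Gaussian taps truncated at 4σ, normalized
  to unit sum, with half-sample symmetric boundary reflection — this
  conserves total intensity to well within 0.1% and commutes with
  midplane reflection.
* **Permutation p-values.** The plain fraction
  $\#\{\text{null} \ge \text{observed}\}/m$ per the definition used
  with cross-validated accuracies; the $(b+1)/(m+1)$ estimator is
  available via `plus_one = TRUE`. All relabelings are drawn before the
  first pipeline call so that seeded fold shuffles inside the pipeline
  cannot couple consecutive permutations.
* **t-maps.** Pooled-variance two-sample t per voxel
  ($\mathrm{df} = n_1 + n_2 - 2$); zero-variance voxels get $t = 0$ and
  a flag. z-scores preserve the one-sided tail probability
  ($P(Z > z) = P(T > t)$, computed on the log scale for stability).
  Suprathreshold voxels (uncorrected $p < 0.001$ by default) are
  clustered with 26-connectivity; cluster volume is voxel count times
  voxel volume.
* **Fold construction.** Folds are stratified by class (with 24-member
  classes, unstratified 10-fold splits can lose a class from a training
  partition) by dealing shuffled class members round-robin with a fold
  pointer that continues across classes, so fold sizes and per-class
  counts both differ by at most one.

## Design decisions on genuinely open points

* **Positive class.** The non-idiopathic pool (MSA ∪ PSP) is treated
  as the positive/sensitivity class. This is an inference: printed
  sensitivities in the literature for this design are consistent with
  rates over the 48 non-idiopathic subjects (77.08% = 37/48) and
  specificities with the 39 idiopathic ones (69.23% = 27/39).
* **Signed vs absolute weights.** Region importance averages $|w|$:
  importance maps are reported on a [0, 1] scale, and signed averaging
  could cancel within a region. A signed variant sits behind
  `signed = TRUE`.
* **Laterality.** Bilateral structures are merged (putamen = L ∪ R) by
  default, with `merge_lr = FALSE` available; "striatum" is an alias
  for putamen ∪ caudate.
* **Grid-search validation.** The inner protocol is a 5-fold CV on the
  training partition — tuning on the outer test fold would leak.
* **Intensity normalization population.** Masked by default;
  `mask = NULL` gives the whole-volume variant.
* **Effect model.** Multiplicative uptake factors, matching
  tracer-binding semantics, rather than additive shifts.

## Problem sizes used by the test-suite simulations

The packaged checks run, by choice, at sizes where each property is
already stable: solver/oracle agreement on 50 random problems with
$n \le 20$; region-selection recovery on 20 cohorts of 35 subjects
(200 outer folds); pipeline discrimination and label-shuffle collapse
on 60 subjects with the full default grid; type-I error of the
permutation test on 200 null cohorts of 30 subjects at 99 permutations
each (the null check averages several relabelings, since a single CV
run of a discrete accuracy is noisy); registration recovery over 20
random perturbations within 8 mm / 8°. The acceptance script runs the
full protocol on the default 39/24/24 cohort with 99 permutations for
the significance step.

## Known limitations

* The affine registration is intensity-driven MSD only — adequate for
  same-modality phantoms, not a substitute for mutual-information
  registration across modalities.
* No nonlinear warping; volumes must share orientation conventions
  (the first grid axis is left-right everywhere).
* Kernel weights come from a grid search, as in the protocol being
  modelled; no gradient-based MKL weight learning.
* Voxel inference is uncorrected; no family-wise or FDR control, no
  random-field cluster p-values.
* Phantom realism is structural, not physical (see above), so absolute
  accuracy figures on phantoms should not be compared with clinical
  results.
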