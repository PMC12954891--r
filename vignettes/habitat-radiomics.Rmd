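---
title: "Habitat radiomics of DCE-MRI perfusion heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics of DCE-MRI perfusion heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

HER2 status in breast cancer is now treated as a three-level variable —
HER2-zero (IHC 0), HER2-low (IHC 1+ or 2+/FISH−), and HER2-positive (IHC 3+
or 2+/FISH+) — because HER2-low disease responds to modern antibody–drug
conjugates. `habitomics` implements a non-invasive imaging pipeline for that
ternary classification built on *habitat imaging*: instead of extracting
radiomics features from the whole tumor, the tumor is first partitioned into
perfusion-defined subregions ("habitats") that are expected to track
vascular and microenvironmental phenotypes, and features are extracted per
habitat.

The pipeline has seven stages, each an exported module:

1. **phantom** — synthetic DCE cohorts with planted habitats (testability);
2. **perfusion** — semiquantitative parametric maps from three DCE phases;
3. **habitats** — pooled k-means subregion discovery and assignment;
4. **features** — per-habitat radiomics (shape, first-order, texture,
   filtered derivatives), imputation, z-scoring;
5. **selection** — ANOVA → Pearson-redundancy → multinomial LASSO cascade;
6. **classify** — SMOTE-rebalanced, grid-searched gradient boosting with
   one-vs-rest ROC evaluation;
7. **explain** — exact tree Shapley attributions, global summaries and
   per-patient waterfalls.

# Perfusion model

From the pre-contrast, early (~2 min) and delayed (~6 min) phase signals
$S_\mathrm{pre}, S_\mathrm{early}, S_\mathrm{del}$, the package computes the
standard semiquantitative enhancement parameters at every tumor voxel:

$$
\mathrm{WI} = \frac{S_\mathrm{early}-S_\mathrm{pre}}{S_\mathrm{pre}+\varepsilon},\qquad
\mathrm{WO} = \frac{S_\mathrm{del}-S_\mathrm{early}}{S_\mathrm{early}+\varepsilon},\qquad
\mathrm{WOR} = \frac{S_\mathrm{early}-S_\mathrm{del}}{S_\mathrm{early}-S_\mathrm{pre}}.
$$

These are one common convention for wash-in, wash-out and the wash-out
ratio; other sign/normalization conventions exist, and the formulas are
isolated in `compute_perfusion_maps()` precisely so a user can substitute
their site's definitions. All three are dimensionless and invariant to a
common rescaling of the phases, which is why absolute phantom signal units
are arbitrary.

Numerical choices:

* $\varepsilon$ defaults to $10^{-6}\times$ the in-mask median of
  $S_\mathrm{pre}$. It stabilizes the ratios on noisy data; identity tests
  of the noise-free inversion pass an explicit tiny $\varepsilon$
  ($10^{-12}$) because the mathematical identity is the
  $\varepsilon\to 0$ limit.
* Voxels with $|S_\mathrm{early}-S_\mathrm{pre}|\le\varepsilon$ (flat
  curves) have an undefined WOR and are **excluded** from the valid mask
  rather than clamped — clamping would inject unbounded outliers into the
  clustering stage. Such voxels are still assigned a habitat later, using
  the two defined dimensions only.
* Order of operations: (optional external N4 bias correction) → isotropic
  resampling (trilinear for images, nearest-neighbor for masks, half-open
  voxel convention, 1 mm default) → perfusion maps on **raw** resampled
  intensities → z-normalization only for the radiomics input image.
  Normalizing before the ratio computation would destroy the ratios'
  meaning. Phantoms carry no bias field, so the pipeline runs with N4
  disabled.

# Habitat discovery

Voxel vectors $(\mathrm{WI}, \mathrm{WO}, \mathrm{WOR})$ are pooled across
the **training cohort only** (default cap 2000 voxels per patient, sampled
uniformly with a logged seed, which bounds memory and keeps large tumors
from dominating), standardized per dimension (the three parameters live on
different scales), and clustered with k-means for $k = 2..10$
(`nstart = 10`). Model selection uses the silhouette coefficient (higher
better) with the Davies–Bouldin index reported alongside (lower better);
when the two disagree the silhouette wins and a divergence warning is
logged. On pools beyond 5000 points the silhouette is computed on a seeded
5000-point subsample — it is an $O(n^2)$ statistic — while the
Davies–Bouldin index, which is linear in $n$, uses the full pool.

Design choices that the underlying study leaves open, resolved here:

* **Population-level clustering.** One model is fit on pooled training
  voxels and applied to every patient (including external test cohorts,
  whose voxels are never pooled into fitting). Cohort-wide habitat naming
  ("Habitat 1..k") and the imputation of features for habitats absent in a
  patient are only coherent under a shared model.
* **Canonical label order** = ascending centroid wash-in (ties: ascending
  wash-out), so habitat identities are reproducible across refits.
* A $k$ whose solution has coincident centroids or degenerate clusters is
  disqualified rather than scored.

`assign_habitats()` labels every tumor voxel by the nearest standardized
centroid; each patient's labels partition the tumor exactly.

# Radiomics features

Per habitat, `extract_region_features()` computes:

* **shape** (10): voxel volume, surface area, surface/volume, sphericity,
  maximum 3-D diameter, PCA axis lengths, elongation, flatness. Surface
  area uses the exposed-voxel-face count with a $2/3$ Crofton-type
  correction, which is asymptotically unbiased for smooth convex digitized
  bodies (a digital ball of radius 10 scores sphericity ≈ 0.99).
* **first-order** (18) with population moments, plus histogram entropy and
  uniformity at a fixed bin width;
* **texture**: GLCM (18), GLRLM (16), GLSZM (16), GLDM (14), NGTDM (5),
  all in 3-D with the 13 unique 26-connectivity directions merged into a
  single matrix per family (the "merged" aggregation variant);
* everything except shape is repeated on the filtered derivatives:
  scale-normalized Laplacian-of-Gaussian images at
  $\sigma \in \{2,3,4,5\}$ mm and the eight sub-bands of an undecimated
  single-level coiflet-1 wavelet decomposition, yielding feature names such
  as `wavelet_HLL_firstorder_Skewness` and
  `log_sigma_2_0_mm_3D_glrlm_ShortRunEmphasis`.

This yields 1141 features per region with the default configuration; the
structural invariant enforced and tested is that the feature-matrix column
count always equals $k \times$ (per-region count). The extraction source
image is the z-normalized early-phase image (tumor ROIs are conventionally
drawn on the early phase) scaled by 100 so that a bin width of 25 produces
a usable grey-level range; regions under 8 voxels cannot support the
texture matrices and are treated as missing.

Missing habitat blocks are imputed with a KNN scheme (default 5
neighbors): distances are computed over mutually observed columns after
standardization by training statistics, the neighbor pool is the
**training rows only** (no test–test leakage), and imputed values are
unweighted neighbor means. Final z-scoring uses training-cohort mean and
population sd per column; zero-variance columns are flagged and dropped.

# Feature selection

Three nested stages on training rows only:

1. **ANOVA screen**: one-way F across the three HER2 groups; keep
   $p < 0.05$. The F statistic is the standard between/within mean-square
   ratio (unit-tested against `stats::aov`).
2. **Pearson redundancy pruning** at $|r| < 0.90$ (the dominant radiomics
   convention; the study does not state its threshold), iterating features
   by ascending ANOVA $p$ so pruning is deterministic and the
   better-ranked member of a correlated pair survives.
3. **Multinomial LASSO** (single three-class model rather than three
   one-vs-rest fits, consistent with the single reported feature set),
   $\lambda$ by 10-fold stratified CV at the deviance minimum — the less
   conservative rule, consistent with the fairly large published set — and
   a feature survives iff any class coefficient is nonzero.

Exact survivor counts are data-dependent and are *not* asserted on
phantoms; nesting, oracle agreement and planted-feature recovery are.
When the cascade selects fewer than two features (a realistic outcome on
null data), the pipeline falls back to the ten best-ranked decorrelated
features and flags the run, so evaluation stays defined.

# Classification and evaluation

Class imbalance is handled by SMOTE (5-neighbor interpolation) up to the
majority count followed by random undersampling to exact parity; both are
applied **inside training folds only**, and synthetic rows carry a flag
that the tests audit against validation folds. The classifier is a
regularized gradient-boosted tree ensemble (xgboost, `multi:softprob`,
single thread for determinism) tuned by grid search over
trees {100, 300, 500} × depth {3, 5, 7} × learning rate
{0.01, 0.05, 0.1} × row/column subsampling {0.6, 0.8, 1.0}², which
contains the published optimum (100 trees, depth 3, lr 0.01, 0.6/0.6).
The grid-search metric is mean macro one-vs-rest AUC, matching how
performance is reported.

Evaluation is one-vs-rest per class: AUC as the Mann–Whitney statistic
(ties one half; exactly equal to exhaustive pair enumeration), 95%
stratified percentile bootstrap CIs (2000 replicates by default; the CI
method is a package choice, the study names none), a 3×3 confusion matrix
from argmax probabilities, and per-class OvR-collapsed accuracy,
sensitivity, specificity, precision and F1. Per-class "accuracy" is the
collapsed binary accuracy — within one cohort it differs per class, which
rules out reading it as overall three-class accuracy.

# Explanation

Attributions are computed on the **margin (log-odds) scale**, where tree
Shapley values are exact and additive; the package carries its own
double-precision implementation of the path-dependent tree Shapley
recursion, parsed from the booster's JSON serialization, so the additivity
identity `base + Σφ = margin` holds to machine precision (the boosting
library's float32 contribution predictor is the independent cross-check in
the tests). Inputs are rounded through float32 before the descent so split
routing matches the library bit for bit. Waterfall displays additionally
map the start and end margins through the softmax to the probability
scale, which is how such explanations are usually narrated; the
probability numbers are display transforms, not the attribution scale.
Summary rankings use mean |φ| per class over the training cohort
background.

# The phantom: what it emulates, and what it does not

Each phantom patient is a 32³ voxel grid (1 mm isotropic) containing a
connected, boundary-perturbed ellipsoidal tumor of 6–10 voxel semi-axes.
`k_true` habitats (default 4) are planted as spatially coherent blobs by
competitive region growing from mutually distant seeds — contiguous
subregions, not i.i.d. voxel labels, because real perfusion habitats are
spatially coherent and i.i.d. labels would make the clustering task
unrepresentative. Each habitat carries a kinetic signature
(pre/early/delayed plateau values in arbitrary units) drawn from a library
of distinct enhancement patterns: rapid wash-in with wash-out, plateau,
persistent enhancement, slow weak enhancement, very rapid enhancement.

The HER2 class signal enters in two ways, mirroring the finding that both
composition and texture matter: class-specific habitat **mixing
proportions** (HER2-zero dominated by early-enhancing habitats,
HER2-positive by late/slow ones, HER2-low uniform) and a class- and
habitat-specific **texture scale** — in-habitat noise is spatially
smoothed white noise rescaled to the nominal sd, so its correlation length
varies by class. Acquisition noise is additive Gaussian (default sd 5 a.u.
against a minimum inter-signature separation of 60 a.u.); i.i.d. when the
texture scale is zero, which is the regime the central-limit sanity tests
use. `null_class_effects()` removes the class signal entirely and is the
null control: the end-to-end pipeline then scores chance-level AUC.

What the phantom does **not** emulate: pharmacokinetic (Tofts-style)
contrast dynamics, coil/bias fields, field-strength or vendor effects,
inter-reader segmentation variability, and the biological overlap that
makes real HER2 classes hard. Consequently, passing phantom tests
demonstrates that the pipeline's machinery is correct and leak-free — that
planted structure is recovered and null structure is not invented — but
phantom AUCs (typically near 1.0 with the default effect sizes) say
nothing about clinical performance, and the published multicenter AUCs are
not reproducible from synthetic data.

# Problem sizes and determinism

Default study conditions run end to end in a few minutes on one CPU: a
90-patient training cohort plus a 45-patient external test cohort at 32³,
~180k pooled voxels, nine candidate k values, 1141 features × k habitats,
the full 243-point hyperparameter grid with 3-fold CV, and 20-phantom
recovery sweeps at 24³ with 3 patients each. All randomness flows from one
global seed through named per-stage substreams (`derive_seed`), so every
stage is independently reproducible and the run manifest's content hashes
are identical across reruns.

# Known limitations

* The perfusion formulas are one convention; sites using different
  wash-out-ratio definitions should swap them in before comparing maps.
* The radiomics extractor covers the major IBSI-style families but is not
  a certified IBSI implementation; per-region counts differ from other
  extractors' catalogs (1141 here), which is why only the
  $k \times F$ column identity is asserted.
* Silhouette subsampling above 5000 pooled voxels trades a little
  selection stability for tractability; the Davies–Bouldin index is
  always computed on the full pool.
* With `stratified = TRUE` (default) phantom class counts are allocated
  deterministically; sampled allocation is available but re-stratifies
  when a class comes out empty at n ≥ 30.
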