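---
title: "Methods: biventricular shape atlas and outcome modelling"
author: "bivatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biventricular shape atlas and outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bivatlas` analyses corresponded biventricular surface meshes at
end-diastole (ED) and end-systole (ES): volumetrics, regional right
ventricular (RV) parcellation, a PCA shape atlas, calliper
morphometry, and a cross-validated linear-discriminant risk score for
adverse events. This vignette records the model assumptions, the
tunable parameters, the numerical choices, and what the synthetic
cohort generator does and does not emulate.

## Data model and assumptions

A subject is a `biventricular_model`: two `surface_mesh` objects (ED,
ES) with identical topology — the same triangle list, vertex count and
per-vertex anatomical labels (`lv_endo`, `lv_epi`, `rv_free_wall`,
`rv_septum`) — plus five landmarks per phase (mitral, tricuspid and
pulmonary valve centroids; LV and RV apices). Point correspondence
across phases and across subjects is assumed to have been established
upstream (template fitting); every statistic in the package leans on
it. Each chamber surface must be watertight (every edge shared by
exactly two faces) and outward-oriented (positive signed volume);
`validate_mesh()` enforces both and rejects degenerate (zero-area)
triangles. All coordinates are millimetres; volumes are reported in
ml, mass in g, indexed quantities per m² of body surface area (BSA).

Cavity volume is the divergence-theorem signed-tetrahedron sum, which
is *exact* for a closed polyhedron, origin-independent, and flags
orientation errors by sign. Papillary muscles and trabeculae are not
represented: the cavity is everything inside the endocardial surface,
which matches the segmentation convention the meshes are assumed to
follow. LV mass uses a myocardial density of 1.05 g/ml (the
conventional CMR value; `density` argument). BSA is consumed as a
cohort-table column; `bsa_mosteller()` is the fallback when only
height and weight are known.

## RV parcellation

RV vertices are assigned to the region of their Euclidean-nearest
landmark — tricuspid centroid → inlet, pulmonary centroid → outlet, RV
apex → apical — with the fixed tie priority inlet > outlet > apical so
results are deterministic. Faces take the majority region of their
vertices (same priority on ties). Regional volume is the signed
tetrahedron sum of each region's face set about a fixed reference
point, the RV ED cavity centroid; because each face is counted exactly
once, the regional volumes telescope to the total RV volume to
floating-point accuracy, which the tests assert at 1e-9 relative.

Two open choices were resolved as follows. First, the assignment is
computed on ED and propagated to ES through the vertex
correspondence, so regional stroke volume compares the *same material
region* across phases; reassigning at ES would mix material points.
Second, the reference point for the signed tetrahedra is the ED
centroid in both phases; any fixed point gives the same totals, and a
phase-fixed point keeps the decomposition exact.

## Shape atlas

ED shapes are aligned by generalized Procrustes analysis (GPA):
starting from subject 1 as reference, every ED is aligned to the
evolving mean by a least-squares rigid transform (Kabsch, proper
rotation enforced by the determinant correction; no scaling, because
size is a legitimate component of remodelling and must stay in the
modes), iterating until the mean moves < 1e-6 mm RMS or 100
iterations. Each subject's ED transform is applied unchanged to its
ES mesh and landmarks, preserving the ED→ES motion. The GPA objective
(mean squared distance to the mean) is non-increasing by
construction, and a cohort of identical shapes under arbitrary rigid
poses re-aligns to machine precision; both are tested.

PCA runs on the mean-centred concatenated ED+ES coordinate vectors
(all three surfaces enter; length 6V). Eigenvalue k is d_k²/(n−1)
from the SVD; modes with explained fraction > `retention` (default
0.01) are kept; z-scores divide the mode loading by √λ_k, so training
scores have mean 0, SD 1 exactly. Mode signs are fixed by making each
mode's largest-magnitude coordinate positive — PCA signs are otherwise
arbitrary and figures depend on them. No per-coordinate variance
normalisation is applied before PCA (raw mm covariance), the standard
choice for point-distribution models. Projection of a new subject
first rigidly aligns its ED block to the mean ED shape (the
population frame) and carries the ES block along.
`synthesize_shape()` reconstructs mean + m·Σ dir_k √λ_k mode_k and
splits it back into meshes, which is how "± 2 SD" mode illustrations
and risk-direction archetypes are produced.

## Calliper morphometry

The anatomical frame per phase: LV long axis mitral-centroid → LV
apex; RV long axis tricuspid-centroid → RV apex; septal normal = the
smallest-eigenvector of the `rv_septum` vertex scatter (error if the
septum is collinear), oriented LV→RV; anterior–posterior (AP) axis =
unit cross product of septal normal and LV long axis. One published
figure caption defines the LV height as running to the *RV* apex; we
read that as a typo and use the LV apex.

Heights are valve-centroid-to-apex distances. At 1/4 (apical), 1/2
(mid) and 3/4 (basal) of the height from the apex, the chamber is cut
by the plane orthogonal to its long axis, and the width is the extent
of the intersection points projected on the septal normal
(septal–lateral) or the AP axis. Projection extent is the
rotation-invariant generalisation of the point-to-point calliper
distances in the source figures; all calliper measures are invariant
to rigid motion to 1e-6 relative (tested), sphericity and
eccentricity additionally to uniform scaling. An empty slice (plane
missing the mesh) is an error rather than an NA, since it indicates
inconsistent landmarks. Displacements (apex, valve centroids, ED→ES)
are Euclidean distances in whatever frame the model is expressed in;
the pipeline computes them after GPA so they live in the common atlas
frame. Mode interpretation regresses each standardized calliper
measure on all retained z-scores by OLS; with orthonormal scores the
coefficients reduce to simple covariances, which is tested.

## Risk modelling

Features are z-scored before any discriminant fit ("standardised and
normalised" is interpreted as one operation). The LDA weight vector
is Σ_pooled⁻¹(μ₁ − μ₀) with the score centred at the pooled-mean
midpoint; a singular pooled covariance (which legitimately occurs —
stroke volume is an exact linear combination of EDV and ESV inside a
pool) is ridge-regularized with λ = 1e-6·trace/d and a warning.

Feature selection is an exhaustive search over all subsets of size
1–3, scored by mean AUC over stratified 4-fold cross-validation with
seed-fixed folds (class counts per fold within 1). At ≤ ~20 candidate
features this is ≤ ~1.5k fits, cheap, reproducible, and never worse
than greedy stepwise search, which is why it stands in for the
unspecified "automatic feature selection algorithm". Ties prefer the
smaller subset, then lexicographic feature order. The staged analysis
runs the search per pool — conventional, regional, shape modes — and
then on the union of the three winning sets; both cross-validated and
in-sample AUC are reported for every stage because the source
material is ambiguous about which one its composite figure is.

The biomarker evaluation uses the Mann–Whitney AUC (ties ½), the
Youden cut-off maximised over observed score thresholds (predicted
positive means score ≥ threshold; ties resolve to the lower
threshold), and an odds ratio from univariable logistic regression
with Wald 95% CI. The OR is reported per 1 SD of the score (the
natural unit for a standardized-feature score) and additionally per
raw unit, which for a binary score equals the 2×2 cross-product ratio
— the form the exact tests check.

Group-comparison tables report mean ± SD with Welch's t-test, or
median (IQR) with Mood's median test for features flagged non-normal.
Mood's test dichotomises at the grand median (values equal to the
median count as "not above") and uses the Pearson chi-square without
continuity correction, matching the hand-computable 2×2 form asserted
in the tests. No multiple-testing correction is applied, consistent
with single-table descriptive use. PRVI analysis is linear, not
discriminant: PRVI is continuous, so "the shape pattern associated
with PRVI" is a forward-selected linear regression on mode z-scores
(partial-F entry at p < 0.05, at most 3 modes), alongside AUC
comparisons of the composite score with and without PRVI on the
subjects for which PRVI exists (complete-case, ≥ 10 required).

## The synthetic cohort generator

The generator exists so that every downstream stage has ground truth.
Its defaults *are* the study conditions the package targets: 192
subjects with an expected 16 adverse outcomes (the published class
imbalance), BSA ~ N(1.59, 0.3) m², QRS ~ N(147, 23) ms, blood
pressures at their published means, PRVI available for ~82% of
subjects with mean ~25 ml/m², and contraction calibrated so the
measured global and regional EFs land at the published cohort means
(RVEF ≈ 37%, inlet/outlet/apical EF ≈ 38/28/38%, LVEF ≈ 52%). The
template is sized for LVEDV ≈ 140 ml, RVEDV ≈ 210 ml and LV mass
≈ 108 g at BSA 1.59 — a dilated RV typical of the population.

Geometry: the LV endocardium and epicardium are truncated prolate
spheroids closed by a flat basal cap; the RV is a crescent
(elliptical free wall, flattened septal side near the x = 0 plane)
lofted along the long axis, closed by an apex pole and a base cap
with an interior ring so the tricuspid and pulmonary landmark
vertices can sit inside the cap. Watertightness and orientation hold
by construction and are asserted for extreme (± 4 SD) latent draws.

Shape variation: up to three orthonormal displacement fields — LV
basal dilation, RV apical dilation with basal constriction, global
size — are projected off the rigid-motion tangent space (translations
and infinitesimal rotations) before Gram–Schmidt, so Procrustes
alignment cannot absorb any part of them. Latent factors multiply
these unit-norm fields with SDs given in mm of shape-vector norm
(defaults 30, 20, 10). The latent matrix is drawn by moment matching
(iid normals, then centred and whitened — the device behind
`MASS::mvrnorm(empirical = TRUE)`): the per-cohort sample covariance
equals diag(latent_sd²) *exactly*, so the variance structure the
atlas is supposed to recover is forced by construction rather than
subject to √(2/n) sampling scatter. This is the one place the
generator departs from pure per-subject substreams: the latent matrix
comes from a cohort-level stream (and therefore depends on n), while
all other subject-level draws remain keyed by subject counter.

Contraction: ES = ED scaled radially toward the chamber long axis
(factor √((1−c)/s_l) with c the prescribed volume-reduction fraction)
and longitudinally by s_l = 1 − shortening (default 0.15) about a
fixed point just below the apex — an affine map, so with uniform
regional multipliers the measured EF equals c exactly (the generator
test pins EF 0.40 to ± 0.01). RV regional multipliers act through a
smooth nearest-landmark-weighted field (exp(−d/15 mm) weights);
because the basal regions carry more cavity volume, multiplier
defaults (1.07, 1.25, 0.89) were calibrated against measured regional
EFs rather than set analytically. The LV epicardium contracts with a
radial factor solved per subject so the myocardial shell volume is
conserved (incompressible myocardium), giving a realistic ES
mass-to-volume ratio.

Outcome and PRVI: adverse outcome ~ Bernoulli(logistic(b₀ + 0.8·z₁/σ₁
+ 1.0·a)), where a is the standardized apical-contraction jitter —
i.e. risk increases with LV basal dilation and with weaker apical
contraction, the qualitative high-risk signature. b₀ is calibrated by
Gauss–Hermite quadrature so the mean outcome probability equals the
target prevalence (16/192 by default). PRVI = 25 + 10.6·z₂/σ₂ +
N(0, 10.6), clipped at 0: R² against its driving latent is 0.5 by
construction, and PRVI is independent of the outcome drivers, so the
"PRVI adds no discriminative value" conclusion has a ground-truth
analogue.

What the generator does **not** emulate: real wall-thickness
variation, trabeculation, valve orifices as true openings, outflow
tract geometry, scanner- and observer-dependent segmentation error
structure (noise is iid Gaussian per vertex, default 0.5 mm), or any
causal link between PRVI and outcome. Passing tests therefore
demonstrate correctness of the *computational pipeline* under known
latent structure, not clinical validity on patient data.

## Numerical choices and degenerate inputs

* GPA: tolerance 1e-6 mm RMS on the mean, cap 100 iterations,
  initialisation at subject 1; reflections never returned.
* PCA: singular values below 1e-12 of the largest are treated as
  zero; zero-eigenvalue modes are excluded from projection.
* Tie-breaks: parcellation priority inlet > outlet > apical at both
  vertex and face level; selection ties → smaller subset, then
  lexicographic; Youden ties → lower threshold.
* Degenerate inputs that raise errors rather than guessing: missing
  landmark keys, ED/ES topology mismatches, non-watertight chambers
  (offending edges are named), inverted epi/endo surfaces, collinear
  septum, empty calliper slices, constant PRVI, single-class labels,
  fewer than 3 positive outcomes.
* Pipeline reruns with the same config and seed are bit-identical;
  the manifest stores md5 checksums of every stage output, and the
  config schema rejects unknown keys.

## Validation protocol and problem sizes

The test suite validates against independent oracles: closed-form
icosahedron and ellipsoid volumes, analytic ellipse cross-sections
for the callipers, brute-force nearest-landmark scans, brute-force
ROC enumeration and 2×2 odds ratios, covariance eigendecomposition,
`MASS::lda` and `pROC::auc` as external cross-checks. Statistical
recovery is exercised at the sizes where the properties are sharp but
cheap: latent recovery on a noise-free cohort of 200 (three modes,
9:4:1 variance shares within 2 points absolute, sub-degree principal
angles after quotienting the common rigid frame, |r| > 0.99 against
the true latents); risk-feature recovery on 20 replicates of n = 400
feature-level cohorts at 25% prevalence (both planted drivers found
in ≥ 80% of replicates). The permutation-null check for the
cross-validation machinery fixes the candidate pool to the two
drivers: searching a larger pool under permuted labels has a known
optimistic bias (selection over many noisy AUCs), which is asserted
separately as its own property rather than allowed to contaminate the
null. The end-to-end run uses the full default conditions (192
subjects) and completes in well under a minute on one CPU.

## Limitations

The package starts from corresponded meshes; template fitting,
segmentation and image handling are out of scope. The atlas is
linear — large deformations that bend the shape manifold are
summarised only to first order. Published headline values (15 modes /
85% variance, the specific AUC ladder, OR 2.06, cut-off −0.18) are
properties of 192 unavailable patient exams; on synthetic cohorts the
package reproduces their *form* (mode count of that order, an AUC
ladder where the composite leads, an OR above 2, a near-zero Youden
cut-off) but the exact numbers are cohort-dependent and are not
claimed.
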