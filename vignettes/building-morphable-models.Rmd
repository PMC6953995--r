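---
title: "Building 3D morphable models from raw scan collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building 3D morphable models from raw scan collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphable3d)
```

## The modelling problem

A 3D morphable model (3DMM) is a linear statistical basis of shape (and,
optionally, per-vertex texture) learned from a population of surfaces in
*dense correspondence*: every mesh re-parameterized to the same vertex
count and triangulation, with vertex `i` carrying the same anatomical
meaning everywhere. Once a cohort is in correspondence, shapes are flattened
to vectors `X ∈ R^{3n}`, similarity effects are removed by generalized
Procrustes analysis, and PCA yields a mean `X̄`, an orthonormal basis `U`
and eigenvalues `λ_i`, so that `X* = X̄ + U α` generates new instances and
`α = Uᵀ(X − X̄)` projects any input into the model.

Everything difficult lives in getting a raw, heterogeneous scan collection
*into* correspondence automatically. This package implements the
construction pipeline in five stages — automatic landmarking, non-rigid
template registration, initial PCA, statistical pruning of failures, and the
final model builds — together with the standard evaluation battery and a
fully synthetic test-bed.

## Stage 1: landmarking by rendered-view back-projection

2D facial landmark detection is a mature technology; 3D landmarking is not.
The pipeline therefore renders each mesh from a rig of virtual perspective
cameras and runs a 2D detector on the rendered views. Each view stores,
per pixel, both the RGB texture and the world XYZ of the surface point that
won the z-buffer — so a sub-pixel 2D detection is lifted to 3D by bilinear
interpolation of the shape image (restricted to covered pixels), and
per-view results are composited by keeping, for each landmark, the
detection with the highest confidence (ties resolve to the earliest camera
in the rig, which places the frontal view first).

Choices worth knowing:

* **Camera rig.** Five cameras on a yaw arc (0°, ±30°, ±60°) at 3× the
  bounding-sphere radius, 512×512 pixels, focal length set so the mesh
  spans 80 % of the image. A yaw arc covers the self-occlusions of
  face-like surfaces; the rig, image size and placement are all arguments.
* **Unlit rendering, back-face culling on.** The quantity that matters —
  the shape image — is light-independent, so no shading model is applied.
* **Detector seam.** A detector is any function taking a rendered view and
  returning pixel coordinates, confidences in [0, 1] and labels. Detectors
  that only use appearance read `view$texture`; the synthetic-fixture
  *oracle* detector also reads the camera to project ground-truth 3D
  landmarks, reporting confidence 0 where the z-buffer shows the point
  occluded. Real 2D detector models are deliberately out of scope; the seam
  accepts any of them (`resolve_detector()` loads one from a `pkg::fun`
  string in configuration files).

The landmarking accuracy test is expressed in the natural unit of this
design: the *one-pixel surface footprint*, i.e. the physical size of one
pixel at the rendered distance (about 0.6 mm for the default fixture and
rig). With the oracle detector the composited landmarks recover ground
truth within that footprint, including landmarks occluded in some views.

## Stage 2: dense correspondence by landmark-guided NICP

The template `V` (n vertices, here an analytic face-like surface) is
deformed onto each scan `S` by per-vertex affine transforms
`A = {A_1 … A_n}`, minimizing

```
E(A) = E_d(A) + α E_s(A) + β E_ℓ(A)
E_d  = Σ_i dist²(A_i (v_iᵀ, 1)ᵀ, S)
E_s  = Σ_{(i,j) ∈ ℰ} ‖(A_i − A_j) G‖²_F,   G = diag(1, 1, 1, γ)
E_ℓ  = Σ_i ‖A_{k_i} (v_{k_i}ᵀ, 1)ᵀ − ℓ_i‖²
```

with `ℰ` the template edge set. After an initial similarity alignment by
landmark Procrustes, the stiffness weight `α` is annealed over a schedule;
at each level the algorithm alternates (i) a closest-point correspondence
search from the current deformed vertices with (ii) an *exact* sparse
least-squares solve of the normal equations in all `A_i` — never gradient
steps — so the fixed-correspondence energy is non-increasing across every
inner solve (a property the test suite checks on randomized instances).

Parameter defaults, all exposed in `nicp_config()`:

| parameter | default | meaning |
|---|---|---|
| `stiffness_schedule` | 8 geometric steps, 50 → 0.5 | coarse-to-fine annealing for mm-scale meshes; high `α` ≈ one global affine, low `α` allows local detail |
| `landmark_schedule` | linear 5 → 0 | landmarks guide the early, ambiguous iterations and release at the end |
| `gamma` | 1 | relative weight of translation vs. linear-part differences in `E_s` |
| `inner_tolerance` | 0.1 mm | mean vertex displacement terminating an inner loop |
| `max_correspondence_dist` | 5 × mean template edge length | reject distant closest points |
| `normal_compatibility_deg` | 60° | reject correspondences whose surface normals disagree |

Correspondences whose foot point lies on a *boundary* vertex or edge of the
target are also rejected (the true surface continues past a rim or hole).
Template vertices left without a valid correspondence at the final
stiffness level are positioned by the stiffness term alone — which
interpolates smoothly across holes in the scan — and reported in
`filled_mask`.

The cylindrical-UV + thin-plate-spline route (`cylindrical_uv_embed()`,
`uv_tps_register()`) is included as the classical baseline. Its known
weaknesses are visible in this package's own tests: the cylindrical map
folds at the silhouette and distorts regions that project poorly, which is
precisely why NICP is the pipeline's method of record.

## Stages 3–5: alignment, pruning, models

Generalized Procrustes alignment iterates aligning every shape to the
running mean and renormalizing the mean to a fixed centroid size
(tolerance 1e-7 relative mean change, ≤ 100 iterations). The classical
convention normalizes the mean to *unit* size; the default here scales to
the average centroid size of the inputs instead, so model-frame
coordinates and every downstream error metric stay in millimetres
(`scale_to = "unit"` restores the textbook convention).

PCA is computed by thin SVD of the centered `k × 3n` data matrix — the
`3n × 3n` covariance is never materialized, which is what makes the
construction scale to dense meshes. Truncation keeps the leading modes
explaining 99.5 % of training variance by default. Mode signs are fixed by
making each column's largest-magnitude entry positive, so archives are
bit-reproducible across platforms and run orders.

Pruning adopts the probabilistic reading of PCA: coefficients `α_i` are
independent `N(0, λ_i)`, so the squared Mahalanobis distance
`F(α) = Σ α_i²/λ_i` is χ² with `d` degrees of freedom, and a shape is
implausible when `F` exceeds the inverse-CDF threshold at `p_f = 0.99`.
One construction-time subtlety: some printings of this statistic show a
fixed `λ_d` denominator; the definition implemented normalizes each
coefficient by *its own* eigenvalue, which is the only reading under which
the statistic is χ²-distributed. Eigenvalues below `1e-12 × λ_1` are
excluded from both the sum and `d`. Pruning is a single pass — initial PCA
on everything, score, exclude, rebuild — and the flagged fraction on clean
Gaussian cohorts calibrates to `1 − p_f` (verified at several `p_f` with
binomial tolerances). A subtlety worth stating: at `p_f = 0.99` a clean
cohort of 200 still produces about 2 false alarms *by design*; "no false
positives" is not a property a fixed-level χ² screen can promise.

Demographically bespoke models mirror the six-group layout common for
large face cohorts — Black, Chinese, and the White group split at ages
7/18/50 — with half-open age bins `[lower, upper)` and a global fallback
for unmatched records.

## The synthetic test-bed

There is no public scan cohort to validate against, so the package
generates one with known ground truth. The base surface is analytic: a
curved cranial dome with a nose ridge, eye sockets, brow ridges and a mouth
groove built from smooth bumps, sampled on a regular parameter grid
(`8·2^res + 1` per side; resolution 1, 289 vertices, for most tests).
Because the surface and all displacement fields are closed-form functions
of the face parameterization, dense correspondence, landmark positions and
mode coefficients are known exactly at any sampling density.

What the generator emulates, per subject: Gaussian low-frequency shape
modes (five by default, 3 … 1 mm RMS); demographic groups with their own
smooth mean-offset fields, age distributions and the gender/ethnicity mix
reported for large real cohorts; capture noise (0.15 mm per coordinate, a
sub-mm structured-light device class); holes; *independent re-triangulation*
of every raw scan on its own jittered parameter grid (so targets genuinely
differ from the template in vertex count and topology); rigid pose jitter
(±10°, ±20 mm); and 44 named landmarks emulating the density of the
standard 68-point 2D annotation, including the ear-to-ear jawline arc. Raw
scans sample a 12 % larger domain than the template, as real captures
extend past the face crop. An `age_coupling` option ties mode 1 to age for
the classification demonstration; `plant_outliers()` displaces chosen
subjects along mode 1 by a stated number of standard deviations as ground
truth for pruning experiments.

What it does **not** emulate: expression or articulation, photorealistic
texture, scanner-specific artifact patterns (motion blur, specular
dropouts), or anatomically realistic mode shapes — the modes are smooth
trigonometric fields, chosen for exact reproducibility rather than realism.
Passing tests therefore demonstrate the pipeline's mechanics, calibration
and asymptotics, not clinical-grade accuracy on real faces.

## Known limitations: correspondence gauge drift

The most important honest caveat. A closest-point data term constrains the
deformation only in the surface-normal direction; the *tangential* placement
of vertices (the correspondence "gauge") is determined by the stiffness
prior, the landmarks, and the annealing path. Under population-scale
multi-mode warps the registered correspondence therefore slides
tangentially by several tenths of a millimetre up to ~1 mm (worst in
landmark-free peripheral regions), in a way that depends smoothly but
*nonlinearly* on the subject's true coefficients. The test suite decomposes
this directly, by registering one fixed subject surface under resampled
noise and resampled re-triangulation: each nuisance imprints well below
twice the capture noise on the registered shape, while the drift from
ground truth is several times larger than either — the residual is
drift-dominated, not noise-dominated.

The visible consequence, measured by the acceptance machinery rather than
asserted away: the held-out generalization error of a model built from
registered shapes floors near 0.4 mm under the default study conditions —
above twice the injected capture noise. Single low-frequency warps, by
contrast, are recovered to a few percent of the template edge length. No
tested stiffness or landmark schedule, inner-convergence setting, target
density or landmark-coverage change removed the drift; it is a property of
closest-point non-rigid registration itself, worth keeping in mind whenever
sub-half-millimetre claims are made about any pipeline of this family.

## Numerical choices and conventions

* Triangle indices are 1-based internally (the R convention); OBJ (1-based)
  and PLY (0-based) are converted at the I/O boundary. PLY vertex data is
  written as 32-bit floats (the common dialect), colors as 8-bit channels.
* Closest-point queries are exact over all triangles (vertex / edge /
  interior cases via the Voronoi-region classification), with a
  centroid-ball prefilter for speed; nearest-vertex searches are exhaustive
  and chunked. No approximate spatial index is used anywhere.
* The registration system solves `(α MᵀM ⊗ GᵀG + DᵀWD + β D_LᵀD_L) X = b`
  by sparse Cholesky; a disconnected template graph is detected up front
  and reported with its component count rather than surfacing as a
  numerical singularity.
* Fixture populations are drawn under one local RNG seed and restore the
  caller's RNG state; identical specifications are bit-identical.
* Model archives are serialized with R's native format (bit-exact
  round-trip) holding mean, basis, retained and full eigenvalue spectra,
  topology and build metadata.
* Problem sizes used by the test-suite and acceptance runs: resolution-1
  templates (289 vertices), raw scans of ~441 vertices, cohorts of 50–220
  subjects — small enough to run everywhere, large enough for the binomial
  and subspace tolerances quoted above to be meaningful.

## Evaluation protocol notes

Generalization is the mean per-vertex Euclidean distance between held-out
shapes and their truncated projections, computed in the Procrustes-aligned
model frame (alignment removes trivial pose error; the frame choice is the
package's, as the metric is undefined otherwise). Specificity samples the
model Gaussian and reports the mean nearest-neighbour distance to the test
set. The fitting protocol is deliberately simple — landmark similarity
alignment, nearest-scan-vertex pseudo-correspondence, one projection — as
its purpose is comparing models, not fitting algorithms; note that its
vertex-to-nearest-vertex error metric has a floor of about half the vertex
spacing on coarse meshes, and a point-to-surface variant
(`point_to_surface = TRUE`) is provided for resolution-independent reads.
The evaluation crop is a radius of 0.45 × the outer-eye-corner distance
around the nose tip: landmark-relative, hence resolution- and
scale-independent, where a fixed millimetre radius would not be.

Age classification represents each subject by its projection coefficients
and feeds any `fit`/`predict` classifier plug-in (default: a linear SVM via
`e1071`); no learning algorithm is implemented in this package.
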