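# morphable3d

Construction and evaluation of large-scale **3D morphable models** (3DMMs) of
anatomical surfaces — statistical shape and texture models built by PCA over
collections of raw triangle meshes — for morphometrics, computer vision and
craniofacial research. The package implements the fully automatic
construction pipeline end to end:

1. **Automatic 3D landmarking** — each raw mesh is rendered from a rig of
   virtual perspective cameras; each rendered view carries an RGB texture
   image and a per-pixel XYZ *shape image*, so any 2D landmark detector
   (plugged in behind a small interface) can be run on the views and its
   detections back-projected onto the surface and composited across views.
2. **Dense correspondence** — landmark-guided non-rigid iterative closest
   point (NICP): the template is deformed by one 3×4 affine transform
   `A_i` per vertex, minimizing

   `E(A) = E_d(A) + α E_s(A) + β E_ℓ(A)`

   where the data term `E_d = Σ_i dist²(A_i ṽ_i, S)` pulls deformed vertices
   onto the scan `S`, the stiffness term
   `E_s = Σ_{(i,j)∈ℰ} ‖(A_i − A_j) G‖²_F` with `G = diag(1,1,1,γ)`
   penalizes differences between neighbouring transforms, and the landmark
   term `E_ℓ` softly pins annotated vertices. The stiffness weight `α` is
   annealed from a near-rigid regime down to fine deformation, alternating
   exact sparse least-squares solves with closest-point correspondence
   searches. A cylindrical-UV + thin-plate-spline route is included as the
   classical comparison baseline.
3. **Statistical modelling** — generalized Procrustes alignment, then PCA by
   thin SVD: shapes are generated as `X* = X̄ + U α` and any shape is
   projected by `α = Uᵀ(X − X̄)`, `P(X) = X̄ + U Uᵀ(X − X̄)`. Per-vertex
   color is carried by barycentric sampling into a texture model of the same
   form. Demographically *bespoke* sub-models (ethnicity and age bands) sit
   behind a rule-based selector with a global fallback.
4. **Automatic pruning** — registration failures are detected from an
   initial global PCA via the squared Mahalanobis plausibility score
   `F(α) = Σ_i α_i²/λ_i`, which is χ²-distributed with `d` degrees of
   freedom under the model's Gaussian; shapes with `F > θ_f` at probability
   `p_f` (default 0.99) are excluded and the model rebuilt.
5. **Evaluation** — compactness, generalization and specificity curves, a
   nearest-vertex fitting protocol with radial cropping and cumulative error
   distribution (CED) curves, demographic breakdowns, and an
   age-classification demonstration on the shape coefficients.

Because the 3D scan cohorts such models are built from are private, the
package ships a first-class **synthetic fixture generator**: an analytic
face-like surface with named landmarks, Gaussian shape modes, demographic
groups, capture noise, holes, independent re-triangulation and pose jitter —
with exact ground truth for every stage, so the entire pipeline is testable
and reproducible without any data download.

## Worked example

```r
library(morphable3d)

# 1. a synthetic study population with known ground truth
spec <- fixture_spec(n_subjects = 20, seed = 42)
pop <- generate_population(spec)
template <- pop$template
pop$subjects[[1]]$raw_mesh
#> triangle_mesh: 441 vertices, 800 triangles, per-vertex color

# 2. automatic landmarking + dense correspondence for every subject
registered <- lapply(pop$subjects, function(s) {
  cams <- default_camera_rig(s$raw_mesh, image_size = c(256, 256))
  lms <- auto_landmark(s$raw_mesh, cams, oracle_detector(s))
  nicp_register(template$mesh, s$raw_mesh, template$landmarks, lms)
})
registered[[1]]
#> registration_result: 289 vertices, mean surface distance 0.0001354 mm,
#>   0 hole-filled, final energy 0.1151

# 3. similarity alignment, pruning, and the final PCA model
gpa <- generalized_procrustes(lapply(registered, `[[`, "deformed_template"))
result <- prune_and_rebuild(gpa$aligned, p_f = 0.99,
                            subject_ids = sapply(pop$subjects, `[[`, "subject_id"))
result$report
#> pruning_report: 0 / 20 subjects flagged (F > 27.688 at p_f = 0.99, df = 13)
result$model
#> linear_model (shape): 13 modes over 867-dim vectors (20 training samples)
#>   retained variance: 99.57%
```

The registration sits on the scan surface to ~1e-4 mm, no healthy subject is
flagged by the χ² screen, and 13 principal modes explain 99.6 % of the
cohort's variance (5 true generative modes plus capture noise and
residual correspondence variation). `model_instance(result$model, coeffs)`
synthesizes new faces; `model_project()` maps unseen corresponded scans into
the model; `compactness_curve()`, `generalization_curve()`, `specificity()`,
`fit_to_scan()` and `ced_curve()` reproduce the standard evaluation battery.

A thin command-line front end over the same functions is installed at
`inst/cli/morphable3d` with subcommands `synth`, `landmark`, `register`,
`build-model`, `prune`, `evaluate`, `run` (full pipeline from a YAML config)
and `report`.

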