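---
title: "Image-based 3D facial landmarking: models, parameters and testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based 3D facial landmarking: models, parameters and testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemark3d)
```

## The problem

Anatomical facial landmarks — eye corners (endocanthion/exocanthion),
nasion, pronasale, subnasale, gnathion, mouth corners (cheilion) and lip
midpoints (labiale superius/inferius) — summarize facial form for geometric
morphometrics and for dysmorphology phenotyping. `facemark3d` locates these
twelve points on a colored 3D surface scan automatically, by rendering the
mesh through virtual cameras, landmarking the *renderings* with 2D models,
and casting the 2D landmarks back onto the surface. The package also
contains the apparatus needed to evaluate such an algorithm (generalized
Procrustes analysis and error reports) and a dense-registration alternative
(non-rigid ICP of an atlas mesh) for comparison.

## The landmarking pipeline

A scan is assumed to sit in the scanner frame: the subject looks toward +z,
+y is up, units are millimetres. The pipeline (`run_pipeline()`) is:

1. `initial_camera_array()`: five cameras with focal point at the mesh
   centroid (unweighted vertex mean), 50° vertical view angle, up = +y, at
   centroid + (0,0,600), then offset 600 mm in +x, +y, −x, −y. The central
   camera is tried first because the scanner geometry makes a frontal view
   the most likely; the wide view angle makes the array tolerant to how the
   subject was posed.
2. `locate_face()` renders each view until the face detector returns a box;
   `select_best_box()` keeps the highest-confidence one (at most one face
   per scan is assumed; ties break to the first box).
3. `landmarks_from_view()` runs the 68-point landmarker in the box, maps 68
   → 12, and casts each landmark's pixel ray into the mesh
   (`cast_ray()`, exact Möller–Trumbore over all triangles, nearest hit).
4. The frontal camera (`frontal_camera()`): focal point `prn`, position
   `prn + 800 mm · normalize((ch_r − ex_l) × (ch_l − ex_r))`, 20° view
   angle, and roll fixed by aligning the camera's vertical axis with
   `n − ls`. Because only the in-plane component of `n − ls` is meaningful
   for roll, the vector is projected onto the plane orthogonal to the view
   direction before normalization. Steps 3–4 are repeated
   `n_refinements = 2` times; the landmarks extracted from the second
   frontal rendering are the output.

With the anatomical-side convention used throughout (suffix `_r` is the
subject's right, which lies at −x in the scanner frame), the cross product
points *out* of the face, so the camera lands in front of it. This is
asserted by a fixture test rather than assumed.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `image_size` | 512 × 512 px | render resolution |
| `array_distance_mm` | 600 | camera-array offset |
| `array_view_angle_deg` | 50 | array view angle |
| `frontal_distance_mm` | 800 | frontal camera distance from prn |
| `frontal_view_angle_deg` | 20 | frontal view angle |
| `n_refinements` | 2 | frontal camera computations |
| `ray_miss_policy` | `nearest_point` | silhouette-ray handling |
| `ray_snap_mm` | 5 | snap cap for missed rays |

The camera geometry numbers are the algorithm's published operating point.
The render resolution is an engineering choice: at 512 px the frontal
pixel footprint is `2 · 800 · tan 10° / 512 ≈ 0.55` mm, comfortably below
manual inter-observer scatter; it is exposed in `pipeline_config()`.
A landmark ray can graze the silhouette (a chin landmark on a tilted face)
and miss by a sub-pixel amount, so the default policy snaps to the nearest
mesh point within 5 mm; the cap prevents gross snapping, and `"error"` is
available for strict runs. If re-detection in a frontal rendering finds no
box, the whole image is used as the box (the rendering is face-centered by
construction); if frontal landmark extraction fails entirely, the last
successful landmark set is returned with a warning.

### Cameras, rendering and numerical conventions

Image coordinates originate at the top-left corner, x right, y down, and
pixel `(i, j)` has its center at `(i + 0.5, j + 0.5)`; this matches common
image libraries and 2D landmark model outputs and is used everywhere.
Pixels are square; the configured view angle is the vertical one. Rendering
(`render()`) is unlit and z-buffered with barycentric vertex-color
interpolation — the 2D models and the fixture detector consume appearance,
not shading, and an unlit contract keeps every rendering bit-deterministic.
The depth at a foreground pixel is defined as the distance along that
pixel's ray, so `render()` and `cast_ray()` agree exactly (a property
test checks 200 random pixels per render). Triangles touching the region
behind the camera are skipped rather than clipped; scan subjects are far
inside the viewing frustum, so near-plane clipping never arises in this
geometry. Ray/triangle intersection requires a strictly positive hit
distance (`t > 1e-9` mm) and returns the nearest hit only — landmarks are
surface points by construction.

### The 68 → 12 map

The 2D landmarker contract is the 68-point iBUG convention. The twelve
anatomical landmarks are taken one-to-one from indices (0-based) 36/39/42/45
(eye corners), 27 (nasion proxy at the nose-bridge top), 30 (pronasale),
33 (subnasale), 48/54 (mouth corners), 51/57 (lip midpoints) and 8
(gnathion proxy at the chin). iBUG's "left eye" in image coordinates is the
subject's anatomical right. The table is the package's own choice — standard
iBUG semantics support it, but nasion and gnathion are type-2 landmarks with
inherent positional ambiguity — and it can be overridden through
`pipeline_config(index_map = ...)`.

## Synthetic fixtures

`make_face_fixture()` builds a face-like parametric surface: an 80 × 110 ×
70 mm ellipsoid with a 25 mm Gaussian nose bump (width 20 mm) and two 5 mm
eye-socket depressions, sampled on a 100 × 100 latitude/meridian grid
(~19.8k triangles), open at the poles like a real scan. Ground-truth
landmarks are mesh vertices: each canonical landmark direction is snapped to
the nearest vertex, and the pronasale to the highest-z vertex near the nose
apex so it is a genuine local maximum. A disk of vertices (radius 4 mm)
around each landmark is painted with one of twelve reserved saturated marker
colors (`marker_colors()`); everything else is skin-colored. The
`fixture_detector()` recognizes the markers by nearest RGB color within
Euclidean tolerance 0.15, reports one box with confidence 1 when at least 8
distinct marker colors are visible, and sets the twelve mapped 68-point
indices to marker-blob centroids.

Painting markers as vertex colors (not geometry) means fixture tests
exercise exactly the color-rendering/back-projection path that real scans
take. What the fixtures deliberately do *not* model: photorealistic skin,
texture maps (vertex color is the package's single color pathway; texture
atlases should be baked to vertex colors upstream), scanner noise and
holes, and — most importantly — the behavior of pretrained 2D detectors on
real faces. Passing fixture tests therefore validates the geometry,
rendering, projection and bookkeeping, not 2D model generalization, which
must be assessed on real data through the `external_adapter()`.

`make_population()` generates families of deformed fixtures for
population-level tests: each member displaces every vertex radially by a
band-limited random field (ten cosine modes of random orientation,
frequency ~1.5–3.5 cycles per radian, random phase, so the field has zero
mean over the sphere), scaled to ≈5 mm RMS by default — enough shape
variance to be visible at fixture scale while keeping the surface smooth
and the topology intact. Landmarks ride along with their vertices.
`perturb_landmarks()` adds iid Gaussian per-axis noise to emulate human
observers; the mean 3D displacement is then the Maxwell mean `2σ√(2/π)`,
which calibrates the error reports.

## Procrustes analysis

`gpa()` follows the classical superimposition literally: every
configuration is centered and scaled **once** to unit centroid size, the
mean is initialized from the first sample, and the loop alternates rigid
(rotation + translation only, reflections disallowed — landmarks are
chiral) alignment of every sample to the mean with recomputation of the
mean, until the mean moves less than `tol = 1e-8` in Frobenius norm. There
is no re-scaling inside the loop and no full-Procrustes scaling; this keeps
the procedure exactly the once-scaled rigid variant its users expect when
comparing landmark precision. Consequences worth knowing: the converged
mean inherits the *orientation* of the first sample, so permuting the input
order changes the mean by a rotation while leaving its shape and all
Procrustes distances unchanged (the order-invariance test aligns the two
means before comparing); and the mean's centroid size drifts slightly below
1, which is immaterial for distance comparisons. Standard deviations in
error reports use the sample (n − 1) convention.

## Non-rigid ICP registration

`nicp_register()` deforms an atlas mesh with one 3 × 4 affine transform per
vertex, minimizing for each stiffness value α

E(X) = Σᵢ wᵢ ‖Xᵢ v̂ᵢ − uᵢ‖² + α Σ_{(i,j) ∈ edges} ‖(Xᵢ − Xⱼ) G‖²_F,

with v̂ᵢ the homogeneous atlas vertex, uᵢ the closest compatible point on
the target surface (point-to-triangle, not nearest vertex, for resolution
independence) and G = diag(1, 1, 1, γ) weighting the translational column.
Correspondences are rejected (wᵢ = 0) beyond 20 mm, when surface normals
disagree by more than 60°, or when the match lands on the target's boundary.
The inner loop alternates correspondence assignment with the exact sparse
least-squares solve for all Xᵢ jointly (normal equations, sparse Cholesky
with the symbolic factorization reused across iterations), until the mean
per-vertex transform change drops below 1e-4 or 10 iterations; the outer
loop anneals α over 8 geometric steps from 50 to 1. The schedule, γ = 1 and
the rejection thresholds are conventional values from the NICP literature,
exposed in `nicp_config()`; every property the tests assert
(fixpoint, rigid recovery, improvement over the affine initialization, mean
bias) is robust to their exact values.

The registration is initialized by `affine_init()`, the least-squares
affine mapping the atlas landmarks onto the subject landmarks. The
landmarks are *not* used inside the energy when evaluating the registration
— they are the ground truth being predicted. A guide-point term
(`landmark_weight`, `guide_idx`/`guide_targets`) is implemented for
atlas-building workflows, where pinning known correspondences is
legitimate, and is off by default.

Energy bookkeeping: each inner iteration logs the energy before and after
the solve *at that iteration's correspondence set*. The solve is an exact
minimizer of a quadratic, so `e_after ≤ e_before` always — this is the
alternating-minimization guarantee the tests assert. Between iterations the
rejection step can re-activate a previously dropped correspondence, which
adds a positive term; comparing energies across different active sets is
therefore not meaningful in general, though on all test fixtures the
post-solve sequence is monotone as well.

`average_atlas()` builds a mean from registered meshes in dense
correspondence: rigid-only Procrustes alignment of the vertex sets
(translation and rotation; scale is a real anatomical signal in dense
averaging and is deliberately not removed), then the per-vertex arithmetic
mean.

### The mean-shape bias

A regularized registration resists deforming the atlas away from its
initial — i.e. average — shape, so landmarks read off a deformed atlas lie
closer to the population mean than the true landmarks do. The package
reproduces this qualitatively: on a population of smoothly deformed
fixtures, the mean Procrustes distance from the mean of NICP-derived
landmarks is consistently below that of the ground-truth landmarks (a
strict inequality is asserted, not a magnitude, because the size of the
effect depends on the stiffness schedule and the deformation scale). For
shape analyses that care about extreme morphologies this bias matters: it
shrinks exactly the signal of interest.

## Problem sizes used in the checks

The test-suite and `scripts/acceptance.R` run entirely on synthetic data:
the default 10k-vertex fixture for pipeline tests (10 random poses within
±30° yaw / ±15° pitch), a ~500-triangle fixture against a 1000-ray
brute-force oracle, 10 008 noisy landmark instances for the
error-calibration check, a 2 025-vertex fixture for NICP fixpoint/recovery,
and populations of 10–20 members (1 296–1 600 vertices each) for the bias
inequality. These sizes were chosen to exercise every code path at
interactive runtimes; all thresholds asserted by the tests are stated in
the test files themselves.

## Known limitations

* Color is required: the pipeline cannot landmark color-stripped meshes.
* One face per scan; multi-face scenes are out of scope.
* The PLY/OBJ reader handles per-vertex color dialects only (no texture
  atlases, quads, or mesh repair).
* Atlas preprocessing (remeshing, decimation) is expected to happen
  upstream; `average_atlas()` assumes meshes already in correspondence.
* The fixture detector validates geometry, not 2D-model behavior on real
  faces; real-scan accuracy is bounded by the pretrained models supplied
  through the adapter.
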