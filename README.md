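# facemark3d

Fully automatic identification of twelve anatomical landmarks on 3D facial
surface scans, for quantitative craniofacial phenotyping. Sparse facial
landmarks (eye corners, nasion, pronasale, subnasale, gnathion, mouth
corners, lip midpoints) are the raw material of geometric morphometrics and
of computer-aided dysmorphology screening, but placing them by hand is slow
and observer-dependent. `facemark3d` implements an image-based automatic
landmarking algorithm together with the Procrustes evaluation machinery used
to assess it and a non-rigid surface-registration (NICP) comparison method.

## The algorithm

The input is a triangulated surface mesh with per-vertex color, in the frame
of a clinical 3D scanner (subject looking toward +z, +y up, millimetres).

1. **Coarse face location.** Five virtual pinhole cameras (view angle 50°)
   are aimed at the mesh centroid: one 600 mm away along +z and four more
   offset 600 mm in ±x and ±y. Each view is rendered in turn and a 2D face
   detector is applied until a bounding box is found; the highest-confidence
   box wins.
2. **2D landmarking and back-projection.** A 68-point facial landmarker
   (iBUG-68 convention) runs inside the box; twelve of the 68 points are
   mapped to the named anatomical landmarks and each is projected back onto
   the surface by casting its pixel ray into the mesh (Möller–Trumbore,
   nearest hit).
3. **Frontal camera refinement.** From the current 3D landmarks a frontal
   camera is computed: focal point at the pronasale `prn`, position 800 mm
   away along the outward facial direction
   `(ch_r − ex_l) × (ch_l − ex_r)`, view angle 20°, roll aligned with the
   nasion-to-upper-lip axis `n − ls`. The face is re-rendered, re-detected
   and re-landmarked; this is repeated twice, and the landmarks read from
   the second frontal rendering are the result.

The 2D models are pluggable: pretrained detectors (e.g. the dlib models) are
wrapped in an `external_adapter()`, while a deterministic
`fixture_detector()` recognizes colored marker disks painted on synthetic
face fixtures, so the entire geometry pipeline is testable offline with
known ground truth.

For evaluation the package provides generalized Procrustes analysis in the
standard geometric-morphometrics formulation — configurations scaled once to
unit centroid size `S = sqrt(Σᵢ ‖xᵢ − x̄‖²)`, then iteratively aligned to
their evolving mean by proper rigid transforms, with the Procrustes distance
from the mean `d_j = sqrt(Σᵢ ‖x_{ji} − μᵢ‖²)` — plus per-landmark error
tables and observer averaging. The comparison method registers an atlas mesh
onto the scan by locally-affine-regularized non-rigid ICP (one 3×4 transform
per atlas vertex, stiffness annealed over a decreasing schedule) initialized
by a landmark least-squares affine, and reads landmarks off the deformed
atlas; `average_atlas()` builds a mean atlas from registered meshes.

## Worked example

```r
library(facemark3d)

fx <- make_face_fixture()          # synthetic colored face, known truth
lm <- run_pipeline(fx$mesh)        # the automatic landmarks
print(round(landmark_errors(list(lm), list(fx$landmarks))$overall$mean, 3))
#> [1] 0.132
```

The fixture's ground-truth landmarks are recovered to 0.132 mm on average —
about a quarter of the frontal-view pixel footprint
(2 · 800 · tan 10° / 512 ≈ 0.55 mm), which is the resolution limit of the
rendering. The same run from the shell:

```sh
inst/cli/facemark fixture  --out-prefix /tmp/fixt
inst/cli/facemark landmark --mesh /tmp/fixt_mesh.ply --out /tmp/lm.csv
inst/cli/facemark evaluate --pred /tmp/lm.csv --obs1 /tmp/fixt_landmarks.csv --out /tmp/tab.csv
tail -2 /tmp/tab.csv
#> li,0.091616,0.000000
#> Overall,0.131985,0.153465
```

Commands `gpa` and `nicp` expose the Procrustes analysis and the
registration the same way.

## Limitations

The pipeline requires per-vertex color (anonymized, color-stripped scans
cannot be processed), assumes at most one face per scan, and the synthetic
fixtures probe the geometry/rendering path, not the behavior of pretrained
2D models on real faces. See the methods vignette
(`vignettes/image-based-landmarking.Rmd`) for the full model description,
parameter choices and testing rationale.
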