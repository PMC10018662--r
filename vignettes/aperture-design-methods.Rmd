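---
title: "Landmark-based WBRT field aperture design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based WBRT field aperture design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbrtaperture)
```

## The problem

Whole-brain radiotherapy (WBRT) is delivered through two opposed lateral
fields (gantry 90 and 270 degrees). The field aperture — the opening shaped
by the multileaf collimator — must cover the whole brain with a margin,
flash beyond the skin so that setup error and swelling stay inside the
field, reach down to a chosen cervical vertebra, and shield the eyes and
lenses. Clinically this shape is drawn by hand on a digitally reconstructed
radiograph (DRR); `wbrtaperture` automates it from anatomic landmarks and
cross-checks the result with a second, independent pipeline.

Two parallel routes produce the beam's-eye-view (BEV) structures that drive
the design:

* **Approach 1** projects 3D structure masks (brain, eyes, lenses, C1, C2,
  external skin) along the beam axis into the BEV.
* **Approach 2** renders a DRR from the CT volume and delineates the same
  structures directly on the 2D image.

Because the two routes share almost no code or data path, large
disagreement between their apertures is a usable error signal: the package
quantifies it with the Hausdorff distance (HD) and mean surface distance
(MSD) inside a clinical evaluation rectangle and issues a pass/flag
verdict.

## Coordinate conventions

Volumes use a DICOM-LPS-like frame, head-first supine: x runs patient
right to left, y anterior to posterior, z inferior to superior; the
isocenter (brain center) is the origin and the lateral beams travel along
x. The BEV is indexed (u, v): v increases toward superior for both gantry
angles; u increases toward *anterior* at gantry 270 and toward posterior at
gantry 90, which makes the two views exact u-mirrors. All file formats and
landmark coordinates are in millimetres in this frame; pixel units never
leak into artifacts.

## The landmark construction

Nine landmarks A–I define the aperture boundary: HI is the cranial border,
FG the caudal border, AI and EF the anterior borders, GH the posterior
border, and A-B-C-D-E the anterior-caudal cut that shields the orbits.
With `EB` the brain mask dilated by `brain_margin` and bounding boxes taken
of the skin-forehead (external restricted to rows at or above the eye-box
top, so the nose never drives the anterior border), the eye union, the lens
union, and the configured vertebra:

* H and I sit at `v = skin top + skin_flash`;
* G and H at `u = skin posterior extreme − skin_flash`;
* I and A at `u = forehead anterior extreme + skin_flash`;
* B at the eye-box top, with `u(B)` at the posterior edge of the lens box
  (`bc_position = "lens"`), of the eye box (`"eye"`), or their midpoint
  (`"mid"`, the default "moderate distance between the backs of the lenses
  and eyes");
* A directly above B's level on the AI line — at the same v when
  `ab_shape = "horizontal"`, or `ab_diagonal_rise` higher when
  `"diagonal"`;
* C where the vertical ray dropped from B first crosses the EB boundary;
* E at `u = vertebra anterior edge + vertebra_anterior_margin`, on the
  inferior EB boundary (falling back to C's level if the boundary does not
  reach that column);
* D the lowest point of the EB arc walked from C to E
  (`ce_shape = "follow_expansion"`), or the C–E midpoint (`"straight"`);
* F and G at the inferior edge of the configured vertebra (C1 or C2).

`include_orbits = TRUE` removes the anterior-caudal cut: the anterior
border becomes a single vertical line at the face's anterior extreme plus
flash, and B, C, D are reported coincident on it.

The closed polygon is I→A→B→C→(arc)→E→F→G→H; when the arc follows the
expansion it is resampled at ≤ 2 mm spacing, collinear vertices are merged
(0.1 mm tolerance), and the result must be simple with positive area.
The opposed gantry-90 field is the u-reflection about the isocenter axis;
building it from scratch at gantry 90 gives the same polygon, which the
test suite checks.

Defaults (`aperture_config()`) follow the configuration preferred in
multi-institutional physician review: diagonal AB (10 mm rise), BC at the
lens/eye midpoint, CD/DE following the brain expansion, 15 mm brain
margin, 15 mm skin flash, caudal border at C1, orbits excluded. Margins
are validated to 0–30 mm.

## The synthetic phantom

`phantom_spec()` parameterizes a stylized head-and-neck CT: an ellipsoidal
head with a soft-tissue neck cylinder, an ellipsoidal brain wrapped in a
4 mm bony shell, spherical eyes with lenses at their anterior poles, and
two stacked vertebral-body cylinders (C1, C2) separated by a 4 mm disc
space. HU defaults give the DRR usable contrast: air −1000, soft tissue
40, brain 35, eye 20, lens 80, bone 700. Default spacing is 2 mm isotropic
(≈ 10⁶ voxels); noise defaults to 0 so geometry tests are exact.

Two geometric choices matter for the landmark logic and mirror real
anatomy:

* the orbits sit *below* the brain's widest level (eye centers at
  z = −40 mm against a brain of AP semi-axis 69 mm), so the BC line can
  clear the brain while the brain expansion still intersects the dropped
  ray for margins of 10 mm and up;
* the eye's anterior pole sits ~2 mm behind the skin, as in a lateral
  skull view.

The CT (not the masks) is assembled with 4× supersampling along the beam
axis, a partial-volume emulation: without it, ray integrals are quantized
in steps of `spacing × μ` ≈ 2080 HU·mm, which would bury the paired-eye
contrast (≈ 960 HU·mm) under voxelization artifacts that no real CT
exhibits. Masks remain binary at voxel centers; overlaps between solids
are resolved at generation time (eyes carved out of the skull shell,
lenses clipped to eyes, everything clipped to the skin) so the declared
containment invariants always hold.

What the phantom does *not* emulate: soft-tissue heterogeneity, skull-base
foramina, mandible and dentition, couch and immobilization devices, beam
spectrum and scatter. Passing tests therefore demonstrate the correctness
of the geometric pipeline and the viability of the two-approach QA concept
at phantom scale — not clinical segmentation performance on patient DRRs.

## DRR rendering and projection

The parallel-beam model is the default: a BEV pixel of the projected mask
is on iff any voxel along the x ray through its center is on, and the DRR
pixel is the line integral of `max(HU + 1000, 0)` (a water-equivalent
attenuation proxy) times path length, in HU·mm. The parallel model makes
landmark geometry exactly testable and both operations linear/monotone; a
divergent point-source model (SAD 1000 mm, half-voxel ray marching) is
available since clinical DRRs diverge. Sub-pixel structure boundaries come
from marching-squares iso-contouring at level 0.5 with bilinear
interpolation, saddle ambiguities resolved toward the foreground.

## The rule-based DRR segmenter

Approach 2's segmenter replaces a trained contouring network with a
transparent rule chain, scoped to phantom-class images. Its interface —
`segment_drr(drr, hints)` returning the same `structure_set_2d` as
approach 1 — is the exchange point where a learned model could be slotted
in. `segmentation_hints()` derives every threshold from the phantom's HU
map and geometry; nothing is hard-coded to one image:

1. **External**: pixels above an air floor (estimated from the lateral and
   superior image borders, which stay air even when the neck exits the
   inferior field of view) → largest connected component, hole-filled.
2. **Bone**: the residual of a per-row elliptical chord fit (exact for
   cylinders and ellipsoid slices) above ~4 mm of bone-equivalent excess,
   gated to the reliable interior of the chord profile.
3. **Brain**: the largest bone component after small closing is the
   cranium; its filled disk is cut below the row where its width collapses
   to vertebral-column scale, opened wider than a vertebral body to drop
   neck appendages, then eroded by the skull thickness.
4. **C1/C2**: bone below the brain, split into bodies at rows whose bone
   width collapses (which also separates the disc space, robust to tilt),
   ordered superior → inferior.
5. **Eyes**: the squared line integral of a (possibly tilted) ellipsoid is
   an exact quadric in (u, v) including a uv cross term, so a global
   least-squares fit of I² over head rows (bone excluded) gives a
   sub-voxel soft-tissue baseline. The paired eyes appear as an
   attenuation deficit; a template of the expected deficit (eye chord
   minus the lens bright core) is fit by least squares with an intercept
   over an anatomically constrained search region (just anterior of the
   skull edge, lower cranium level), with implausibly strong responses
   rejected, then refined on a 0.5 mm sub-pixel grid.
6. **Lens**: the fitted eye deficit is subtracted from the residual and a
   pure lens-chord template is matched around the eye's anterior pole.

Each mask is post-processed by 3 mm opening/closing and clipped to the
external contour. Any structure that cannot be located raises a structured
`wbrt_segmentation_failure` carrying the missing names — the QA trigger:
the pipeline then still emits the approach-1 aperture and a `"flag"`
report with the reason rather than crashing.

On the default noise-free phantom the segmenter reaches Dice ≥ 0.90 for
every structure against the approach-1 projections (brain ≥ 0.99). With
20 HU CT noise all structures are still found and Dice degrades by less
than 0.05 — except the lens, a 4 mm object on a 2 mm grid whose 960 HU·mm
peak contrast sits close to the ~360 HU·mm ray-noise floor; its noisy Dice
stays above 0.75 but the sub-millimetre localization that the noise-free
case achieves is no longer information-theoretically available. This is a
known limitation, not a defect the aperture inherits: the BC landmark
moves by at most the lens-box error, far below the QA thresholds.

## QA metrics and verdict

HD and MSD are computed on boundary point sets densified to ≤ 0.5 mm
vertex spacing — point-to-point, not point-to-segment, which bounds the
discrepancy against the continuous definition by 0.25 mm. MSD uses the
average-of-both-directed-means convention (the common one in medical
imaging; variants exist, so it is stated). The evaluation rectangle runs
from 5 mm behind the vertebral bodies to 20 mm in front of the forehead,
and vertically from the caudal to the cranial landmark level; both
boundaries are clipped to it. Default thresholds are HD ≤ 10 mm and
MSD ≤ 5 mm — agreeing pipelines on the phantom sit near 2 and 0.3 mm, an
order of magnitude below, so the verdict separates cleanly.

## Numerical choices and degenerate inputs

* Iso-contours at level 0.5 − 1e−9 bias marching-squares saddles toward
  the foreground; grids are zero-padded so contours always close.
* Morphological disks are built per-axis (`round(radius / spacing)`
  pixels), so anisotropic BEV grids dilate isotropically in mm.
* `bounding_box` edges sit at outer pixel borders; a margin of one voxel
  is the stated tolerance of every geometric contract.
* If the vertical from B exits the image before meeting the EB boundary
  the construction errors ("landmark C undefined") rather than guessing.
* Aperture polygons are checked for simplicity (O(n²) segment test) after
  collinear-vertex merging; self-intersection signals inconsistent
  landmarks and is an error.
* Distances below 1 nm in the HD/MSD kernels are clamped to zero so
  coincident densified points compare exactly.
* The posterior border is flashed beyond the skin (symmetric with the
  cranial and anterior borders); whether to place it on the skin instead
  is left configurable by a future option rather than silently changed.
* F–G extends posteriorly to meet the G–H line at the flashed posterior
  border, so the caudal border spans the full field width.

## Problem sizes

The test-suite and acceptance runs use 2 mm phantoms (≈ 82×108×117
voxels), 20 randomized phantoms for the geometric contracts, 10 for the
two-approach agreement, and 100 random polygon pairs against the
brute-force HD/MSD oracle. A single end-to-end pipeline run takes a few
seconds on one core.

## Worked example

```{r example, eval = FALSE}
library(wbrtaperture)

spec <- phantom_spec()            # default stylized head
res <- run_pipeline(spec)         # both approaches + QA
res$qa
#> <qa_report> approach1 vs approach2: HD 1.42 mm, MSD 0.03 mm -> PASS

res$landmarks1                    # the nine landmarks, mm in the BEV
polygon_area(res$aperture1$vertices) / 100   # aperture area, cm^2
```

## Known limitations

* The segmenter is phantom-scoped by design; clinical DRRs would need a
  learned model behind the same interface.
* The divergent-beam mirror identity is exact only for x-symmetric
  volumes; the parallel model's mirror identity is exact always.
* Dose calculation, beam weighting and treatment-planning-system
  integration are out of scope.
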