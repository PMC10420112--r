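---
title: "Parametric plate modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric plate modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records how `plateforge` models the plate-bone contact
surface, which choices were genuinely open, and what the synthetic
validation does and does not demonstrate. The README shows the
user-facing walkthrough; here we concentrate on methods.

## The procedure

The pipeline reduces a bone surface mesh to a small parameter set and
rebuilds the plate from it:

1. **Anatomical frame.** The shaft axis is the total-least-squares line
   through cross-section centroids taken over a configurable axial
   sub-range (default fractions 0.15–0.70 of the principal extent,
   excluding the condylar flare), with one refinement pass re-slicing
   normal to the fitted line. The axis is oriented proximal-to-distal
   by comparing maximal section widths near the two ends: the condylar
   flare makes the distal sections the widest. The posterior direction
   cannot be inferred from a bare, unlabeled mesh (chirality), so it is
   supplied (`posterior_hint`) and orthogonalized against the axis.
2. **Sections and ROI points.** `n_sections` planes normal to the axis
   are placed over the plate span; a `distal_bias` parameter warps the
   spacing by `g(t) = 1 - (1 - t)^(1 + 2 bias)` so density increases
   distally where curvature changes fastest, with endpoints pinned.
   On each contour the *middle* ROI point is the posterior-most point
   (parabolic refinement along the polyline), and the *left*/*right*
   ROI points are the crossings of rays at half the sector angle either
   side of the posterior ray from the section's area centroid.
3. **Arcs and parameters.** The unique circle through (L, M, R) is
   computed in the plane of the three points; the plate parameters are
   the arc's central angle, its centre's distance to the axis, and the
   AP-plane supporting distances of L and R. Everything is serialized
   to versioned JSON at full double precision and re-validated on load.
4. **Surfaces.** The loft evaluates each section's arc by *normalized
   arc length* and joins equal-`v` points across sections with natural
   cubic splines; the alternative subdivision route initializes a
   quad control grid on the loft and conforms it to the bone.
5. **Solid.** The contact surface is offset along outward normals
   (away from the axis — the inner face must remain the bone-fitting
   face), rims are stitched with ruled walls, and watertightness is
   asserted, never assumed.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_sections` | 9 | – | nine sections suffice for plate-level accuracy; more adds cost, not fit (see refinement study below) |
| `sector_angle_deg` | 90 | deg | posterior sector wide enough for a plate footprint without wrapping the cortex; per-section values allowed |
| `distal_bias` | 0.3 | – | denser sampling over the condylar flare |
| `plate span` | 0.40–0.96 of extent | – | distal plate ending short of the articular end (olecranon-fossa clearance is the surgeon's qualitative constraint, exposed through span and sector settings) |
| `thickness` | 2 | mm | usual clinical wall thickness; any positive value accepted |
| `shaft_fraction` | 0.15–0.70 | – | axis fit range excluding flare and head |
| `subd` grid / iters / step | 9×5, 50, 0.5 | – | two subdivision levels for fitting samples balance fidelity and cost |

## The synthetic phantom

`bone_phantom_spec()` emulates the features the pipeline actually
consumes: a tapering elliptical shaft (AP semi-axis 12→10 mm over a
210 mm shaft, ML/AP ratio 1.2), a smooth medio-lateral condylar flare
(42 mm wide over the distal 40 mm, smoothstep blend) rather than two
anatomically literal condyles, a sagittal centerline bow (4 mm), and
Gaussian surface noise along vertex normals (default SD 0.05 mm,
emulating CT-segmentation roughness at 0.5 mm slice resolution). The
generator frame fixes posterior = +Y by construction, so AP logic is
testable against a known answer, and the analytic cross-section
function is the ground-truth oracle for slicing and axis recovery.

What the phantom does **not** model: real cortical ridges and
tuberosities, the olecranon fossa depression, bimodal condyles,
left/right asymmetry, segmentation artifacts (steps, holes), or pose
error. Passing tests therefore show the *geometry processing* is
correct and accurate at clinically relevant scales — not that the
default settings produce a clinically acceptable plate for a given
patient; on real bones the deviation statistics should be expected
closer to the 0.1–0.2 mm range than to the phantom's 0.03 mm, and the
posterior hint and plate span must come from the clinical context.

## Numerical choices

* Units are millimetres throughout; no unit conversion is attempted.
* Vertex-merge tolerance 1e-6 mm (far below CT resolution); degenerate
  faces (area ≤ 1e-12 mm²) are dropped and counted. Validation is
  idempotent.
* STL stores no topology, so watertightness is always recomputed.
  Binary STL is float32: round trips are exact to ≈ 1e-5 mm at the
  coordinate magnitudes used here, which is the documented contract.
* Plane slicing keys intersection points by mesh edge, so the two
  faces sharing an edge get bit-identical points and loops close
  exactly; vertices lying within 1e-12 mm of the plane are nudged to
  keep crossings transverse. Multi-loop slices keep the largest-area
  loop (plates span the main cortex contour) and log the event.
* ROI ray crossings nudge contour vertices that lie exactly on the ray
  (a real occurrence on symmetric meshes) to one side, and take the
  outermost crossing on non-star-shaped contours.
* Arc fitting is the in-plane circumcenter closed form; collinearity
  (triangle area ≤ 1e-9 mm²) is a degeneracy error, not a fallback.
  The arc side is chosen by the middle point, never ambiguous; angles
  in `(0, 2π)` are supported, though plate parameters require `(0, π)`.
* Lofts use *natural* cubic splines in the axial direction — the
  reproducible choice; no claim is made of matching any particular CAD
  kernel's loft. If a stored angle disagrees with the arc through the
  stored ROI points (hand-edited files), the angle wins: the arc is
  re-trimmed symmetrically about its middle point with a warning.
* Catmull–Clark uses the standard face/edge/valence rules with the
  cubic B-spline boundary rule; only vertex positions are degrees of
  freedom (normals are not independent in Catmull–Clark, whatever
  interactive CAD tools expose). The regular-grid limit is verified
  against an independent bicubic B-spline evaluator in the tests.
* The subdivision fit moves each control vertex by `step ×` the
  weighted mean residual of the samples it influences (weights from
  the exact subdivision operator); rejected steps halve the step size,
  five consecutive rejections raise a convergence error. Boundary
  vertices move freely by default; `boundary = "fixed"` pins the rim.
  A rim-curve *sliding* constraint was considered and rejected: it
  cannot reach the documented planar-fit accuracy when the initial rim
  is off the target, and pinning covers the footprint-preservation use.
* Deviation signs are along the reference facet normal (positive =
  query outside the bone); distances are exact nearest-facet, not
  nearest-vertex, which would bias high on coarse meshes. Footprint
  restriction (default) crops the reference to the query's inflated
  bounding box; medians are therefore *footprint* medians, and the
  report records that flag.
* Center-to-axis distances may legitimately be 0 (a centered circular
  shaft), so validation requires `dist ≥ 0`, strictly positive only
  for thickness.

## Problem sizes

The test suite and acceptance script run phantoms at 80 axial × 48
circumferential rings (≈ 7.7k faces), deviation sampling at 400–1500
points, solids at 80 × 24 shells, and subdivision fits on 9 × 5 grids
with two refinement levels (561 samples) — sizes chosen so the full
validation completes on a laptop-class single core in about a minute
while keeping every tolerance meaningfully below the clinical scale
(0.1 mm). A refinement study (3 → 9 → 15 sections) on the smooth
phantom shows the median footprint deviation falling ≈ 0.25 →
0.016 → 0.014 mm and the maximum 0.73 → 0.10 → 0.05 mm — the basis for
the nine-section default.

## Known limitations

* Screw holes, locking threads, fillets and chamfers are out of scope;
  the solid is the blank an implant CAD step would continue from.
* The "Left max / Right max" ROI definition is interpreted as angular
  offsets about the posterior ray (making the sector angle the literal
  plate-width control); extrema of pre-traced anatomical curves are an
  alternative reading, supported by supplying explicit ROI points.
* Single-view projection scaling applies one in-plane factor; it is a
  deliberate approximation (flagged in the API documentation), with
  two-view anisotropic scaling available when both factors exist.
* FFD is exposed as a tool (lattice in, mesh out), not an automated
  registration: template bending has no objective function here.
* The material/manufacturing stage is a metadata stub by design;
  slicing and toolpaths belong to external tools.
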