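# plateforge

Parametric modelling of the contact surface and solid of extra-articular
distal humerus fixation plates (LCP-style), from a bone surface mesh.

## The problem

Extra-articular fractures of the distal humerus are stabilized with
anatomically pre-contoured locking plates. When the plate's factory
shape does not match the patient's bone, the surgeon bends it
intra-operatively — slow, and easy to get wrong. A *personalized* plate
needs a compact, portable description of the bone-facing contact
surface that can be (a) extracted automatically from a 3D bone model,
(b) rescaled to a patient when only a plain radiograph is available,
and (c) turned back into a printable solid.

`plateforge` implements such a description and the full pipeline around
it, for surgeons' engineering teams, implant designers, and anyone
studying parametric implant modelling. No clinical data are needed: a
seeded synthetic humerus generator with analytic ground truth drives
every stage.

## The model

All geometry is measured in an anatomical frame: the shaft axis **a**
(least-squares line through shaft cross-section centroids, proximal to
distal), the posterior direction **p**, and the medio-lateral direction
**m** completing a right-handed orthonormal triple. Along the plate's
axial footprint, *n* cross-sections are sliced (default *n* = 9, which
previous testing showed gives the plate model sufficient accuracy). On
each section contour three region-of-interest (ROI) points are read —
the posterior-most **M**iddle point and the **L**eft / **R**ight points
where rays at ±α/2 from the posterior ray meet the contour — and the
unique circular arc through (L, M, R) is fitted. The plate description
is then

    Opt_ROI    : n x 3 matrix of (L_i, M_i, R_i) points,
    Opt_angles : arc central angles  α_1 … α_n          (plate width),
    Opt_dist   : arc-centre distances d_i to the axis   (plate depth),
    Opt_Sdist  : left/right supporting distances d_il, d_ir — the
                 normal distances of L_i, R_i to the axis in the
                 anterior-posterior plane (single-radiograph rescaling),
    t          : solid thickness (default 2 mm).

From the parameter set the package builds a lofted contact surface
(each section traces its arc exactly; natural cubic splines join equal
normalized-arc-length points between sections), or alternatively a
Catmull–Clark subdivision surface whose control grid is iteratively
fitted to the bone. The surface is thickened along its outward normals
into a watertight printable solid, and signed nearest-facet deviation
analysis quantifies the plate-bone fit. Free-form deformation (FFD)
lattices and projection scale factors personalize a template when only
limited imaging exists.

## Worked example

```r
library(plateforge)

out      <- generate_humerus(bone_phantom_spec(seed = 1))   # synthetic bone
frame    <- compute_anatomical_axis(out$mesh)
stations <- place_stations(frame, c(0.40, 0.96) * frame$extent,
                           n_sections = 9, distal_bias = 0.3)
params   <- assemble_params(out$mesh, frame, stations,
                            sector_angles = 90 * pi / 180, thickness = 2)
print(params)
#> <plate_params> 9 sections, stations 100.1-240.3 mm, thickness 2.00 mm
#>   section station_mm angle_deg dist_mm sdist_left_mm sdist_right_mm
#> 1       1      100.1     66.11   4.081         8.971          8.965
#> 2       2      127.1     67.44   3.747         8.699          8.603
#> 3       3      151.8     67.55   4.123         7.946          8.017
#> 4       4      174.2     67.21   4.875         7.118          7.091
#> 5       5      194.1     67.47   5.633         6.023          6.040
#> 6       6      211.1     67.37   6.515         5.032          5.018
#> 7       7      225.1     46.84  14.307         4.835          4.838
#> 8       8      235.3     32.50  25.345         4.702          4.696
#> 9       9      240.3     30.44  28.049         4.523          4.485
```

The stations crowd toward the distal end (`distal_bias = 0.3`); over
the condylar flare the contours widen, so the fitted arcs flatten —
central angles drop from ≈ 67° to ≈ 30° while the arc centres move away
from the axis (`dist_mm` rises from ≈ 4 to ≈ 28 mm). The supporting
distances shrink distally as the plate hugs the flatter posterior face.

```r
surface <- loft_surface(params)
report  <- surface_deviation(surface, out$mesh, n_samples = 1500, seed = 1)
print(report)
#> <deviation_report> n = 1500 vs 'synthetic humerus (seed 1)' (footprint only)
#>   median -0.0046 mm  |median| 0.0328 mm  max|d| 0.1940 mm
#>   p5 -0.0919  p25 -0.0374  p75 +0.0280  p95 +0.0700

solid <- thicken(surface, 2)
th    <- measure_thickness(solid, surface, n_samples = 200, seed = 1)
#> wall thickness: median 1.996 mm (min 1.994, max 2.000)
write_mesh(solid, "plate.stl")      # watertight, slicer-ready
```

The nine-arc surface tracks the (noise_sd = 0.05 mm) phantom with a
median absolute deviation of 0.033 mm over the plate footprint, and the
thickened solid keeps the prescribed 2 mm wall within 0.4%.

`run_workflow()` chains all of the above (bone → frame → parameters →
surface → deviation gate → solid → material stub → manifest) into a
reproducible artifact bundle; `inst/cli/plateforge.R` exposes each step
as a shell subcommand.

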