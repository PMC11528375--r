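---
title: "Level-set hippocampal morphometry: models, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-set hippocampal morphometry: models, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hippomorph)
```

# The problem and the representation

Manual tracing remains the reference standard for hippocampal
segmentation: a specialist outlines the structure slice by slice on
sagittal MRI, and the stack of closed polygons defines a binary volume.
`hippomorph` converts such tracings into a *signed distance field*
("digital twin"): a scalar grid `phi(x)` in millimetres, negative inside
the structure, whose zero level is the boundary surface. Every
morphological quantity the package reports is read off this implicit
representation or off the triangulated zero-level surface extracted from
it.

Working with a distance field rather than the raw mask has two payoffs.
First, sub-voxel geometry: the zero level is positioned by linear
interpolation between voxel centres, so surface area and diameter do not
inherit the full voxelization error. Second, the interior depth `-phi`
is itself a geometric measurement — the largest inscribed sphere, the
corner radii and the medial structure all fall out of it directly.

## Grid conventions

Voxel `(i, j, k)` (0-based) covers the half-open cube
`[i*s, (i+1)*s)`; its centre sits at `origin + (i + 0.5) * s`. A mask
voxel is `TRUE` iff its centre lies inside the traced polygon (even-odd
rule) or inside the analytic phantom solid. The signed distance is the
exact Euclidean distance transform of both phases with a half-voxel
offset, which places the zero level midway between the last inside and
first outside voxel centre — the unbiased choice when nothing more than
the binarization is known. All internal geometry is in mm; every report
uses the cm-based units conventional in volumetry tables (cm^3, cm^2,
cm).

# The reconstruction chain

1. **Rasterization** (`traces_to_mask`): per-slice polygons, voxel-centre
   membership, OR-combination of multiple polygons, clipping with a
   warning when traces leave the grid.
2. **Component labeling** (`label_components`): a marker-controlled
   watershed on the internal distance transform separates touching blobs.
   Seeds are the h-maxima of the depth map with a suppression depth of
   one voxel — deep enough to ignore discretization bumps, shallow enough
   to keep genuinely separate lobes apart. The largest component is the
   hippocampus candidate.
3. **Denoising** (`nlm_denoise`): 3D non-local means, patch radius 1,
   search radius 3. The filter strength defaults to twice a robust noise
   estimate (the median absolute deviation of the 6-neighbour Laplacian,
   whose variance is 42 sigma^2 on locally flat images), so the same
   defaults adapt to any intensity scale. A constant image is an exact
   fixed point; on the two-level phantoms the interior noise sd drops by
   well over half while the half-max edge position moves by less than a
   voxel.
4. **Level-set evolution** (`evolve_level_set`): distance-regularized
   evolution with an edge-stopping map
   `g = 1 / (1 + (|grad G_sigma * I| / s0)^2)`, a weighted-length term
   that attracts the zero level to edges, a balloon term (negative weight
   = inflation) that closes small gaps between the initialization and the
   true boundary, and a double-well regularizer that keeps `phi` close to
   a distance function without periodic reinitialization. The published
   descriptions of this pipeline do not state evolution parameters, so
   the defaults here are the package's own: sigma = 1.5 voxels,
   mu = 0.2, lambda = 5, alpha = -1.5, dt = 1 (grid units),
   250 iterations, delta half-width 1.5 voxels. The time step must
   satisfy `mu * dt < 0.25`; violating it is an error naming the bound,
   and an evolution that collapses to a single sign aborts rather than
   returning a degenerate twin. The edge scale `s0` defaults to 0.2
   times the 99.5th percentile of the smoothed gradient magnitude, which
   keeps `g ~ 1` in flat tissue and `g << 1` on the boundary without
   manual tuning. Evolution is run in 3D (not per-slice).
5. **Meshing** (`extract_mesh`): marching tetrahedra on the Kuhn
   6-tetrahedron cell decomposition. Because every cell is split with
   the same main diagonal, shared faces triangulate identically and the
   welded mesh is closed by construction (each edge borders exactly two
   triangles; Euler characteristic 2 on phantom shapes). `phi` is
   pre-smoothed by 0.6 voxels before interpolation: the zero level of a
   distance field is nearly linear across the interface, so this barely
   moves the surface (the curvature bias is of order `sigma^2 * kappa`,
   about 0.01 mm here) but removes the voxelization staircase that would
   otherwise inflate surface area by roughly 12%. On a 9.2 mm sphere at
   0.5 mm spacing the measured volume is 0.9% low and the area 1% high.

# The six descriptors

* **Volume / surface area**: signed tetrahedron sum (divergence theorem)
  and triangle-area sum over the closed mesh.
* **Diameter**: twice the radius of the smallest enclosing sphere of the
  surface, computed exactly by Welzl's move-to-front algorithm
  (deterministic under a fixed shuffle seed). For mask-derived fields the
  sphere is fitted to a more strongly anti-aliased extraction
  (sigma = 1.2 voxels) because residual staircase peaks otherwise bias
  the circumscribed radius upward by 1-2%; the radius is floored at the
  equivalent-volume sphere radius, which no enclosing sphere can
  undercut.
* **Sphericity** `S = r_in,max / r_cir,min`: the inscribed radius is the
  deepest interior point of the field, refined by intersecting the two
  unit-slope tent flanks along each axis (a distance field has unit
  gradient, so its peak is a tent, not a parabola — a parabola fit
  under-reads by up to half a voxel when the medial axis lies between
  voxel centres). Discretization can push the measured `r_in` marginally
  above `r_cir` on near-spherical shapes; `S` is clamped at 1 so the
  invariant `S <= 1` holds exactly.
* **Roundness** `R = (1/N) sum r_i / r_cir,min`: the descriptor tables
  this package mirrors normalize by the *circumscribed* radius, which
  makes `R = 1` on a sphere; the classical granulometry convention
  (inscribed radius) is available via
  `roundness(..., denominator = "inscribed")`.
* **Aspect ratio**: extents are ranges of interior-voxel projections onto
  the covariance eigenvectors — length-like quantities that recover the
  full axis lengths `2a >= 2b >= 2c` of an ellipsoid exactly, so
  `AR = c/a` analytically (eigenvalue square roots would only be
  proportional to them).
* **Volume-to-surface ratio**: `V/A` in cm, with the reciprocal `A/V`
  (cm^-1) reported alongside. Published hippocampus tables print
  "volume to surface ratio" values around 7.6-8.3 "cm", which is
  dimensionally consistent with `A/V` for a ~3.3 cm^3 structure, not with
  `V/A` (~0.2-0.3 cm); rather than guess which the authors meant, both
  are computed and the reader picks the convention.

## Corner detection: the one genuinely open design

"Corners" — the locally cap-like patches whose curvature radii enter the
roundness — are not defined operationally in the descriptor literature
this package follows, and the obvious estimator fails at marching-cubes
mesh density: a quadric fit over a vertex 2-ring sees height variations
of ~0.01 mm against extraction noise of ~0.05 mm, and its curvature
estimates scatter over almost an order of magnitude.

The package instead measures the per-vertex corner radius as the
**touching-ball (medial) radius**: trace the steepest ascent of the
interior depth `-phi` inward from the vertex; depth grows at exactly unit
rate until the path reaches the medial structure, and the depth at that
break is the radius of the largest inscribed ball tangent at the vertex,
which on convex caps equals the maximal principal curvature radius. The
read-out is taken from the distance field itself, so its error is bounded
by the half-voxel quantization instead of amplified by differentiation.
Three numerical stages make this robust (`medial_radius`): the ascent
runs on a 0.7-voxel-smoothed copy of `phi` with a one-step grace before a
path is retired; the path is then extended along its frozen direction
while the raw depth still gains at near-unit rate (smoothing under-reads
the peak near point- and line-like medial loci); finally short probes
average the raw depth with the distance back to the start vertex, which
plateaus at the exact radius for point/line loci, and stop as soon as the
raw depth keeps climbing — the signature of a medial sheet, where
continuing would inflate the estimate.

Quadric patch fits survive in one supporting role: the *minor* principal
curvature (patch radius `0.5 r_in`, on a Taubin-smoothed mesh copy)
separates cap-like corners, which are convex in both directions, from
cylindrical ridge walls, whose second curvature is flat. A corner region
is a connected vertex set with touching radius at most
`r_in (1 + 0.15)` — the tolerance absorbs half-voxel surface
quantization — and minor curvature radius at most `2 r_in`; regions
smaller than 0.2% of the mesh are classification speckle and dropped.
On the validation shapes this yields exactly one region covering a
sphere (`r_1` within 4% of the true radius), exactly the two caps of a
capsule (`r_i` within 9% of the cap radius, roundness 0.31 against the
analytic 1/3), and tip-concentrated regions on a 20/15/10 mm ellipsoid
whose smallest vertex radius matches the analytic tip curvature radius
`c^2/a = 5 mm` within 15%.

Known limitation: region composition is lattice-sensitive, so roundness
can swing by ~10% when an anisotropic shape is rotated against the grid;
sphericity and aspect ratio stay within 2%. Descriptor reports should
therefore lean on S and AR for orientation-independent elongation and
treat R as a smoothness indicator.

# The synthetic study

## Phantoms

`make_phantom` voxelizes spheres, ellipsoids, capsules and bent tubes
(the seahorse-like smoke-test shape, which carries no analytic truth)
at arbitrary rigid pose, emitting a two-level intensity image
(inside 100, outside 20, additive Gaussian noise sd 5 by default) and the
ground-truth descriptor set where closed forms exist. The two-level
image with moderate noise gives the denoising and evolution stages a
realistic but fully controlled edge. What phantoms deliberately do *not*
emulate: MRI bias fields, partial-volume averaging, Rician noise, or the
anatomical complexity of a real hippocampus — passing the phantom suite
demonstrates the geometry and the pipeline mechanics, not clinical
segmentation accuracy. The ellipsoid's analytic surface area uses the
Thomsen approximation (p = 1.6075, error below 1.1%), which is tighter
than the 2% mesh tolerance it backs.

## Cohort simulator

`simulate_cohort` emulates the statistical structure of a two-rater
volumetry study of 63 patients (26 male), uniform ages 18-95: one record
per patient x hemisphere x rater. Rater-1 volumes follow an inverted-U
quadratic age law through a peak of 3.7 cm^3 at age 55 and 1.7 cm^3 at
age 90 — two anchors determine the quadratic; the implied young-adult
value (about 1.5 cm^3 at 18) is what the parabola dictates, since no
single quadratic can also match independently reported young-adult
means, and all anchors are configurable. Sex (+0.14 cm^3, male-female)
and hemisphere (+0.325 cm^3, right-left) offsets are applied *centred*
(`offset * (1[M] - p_male)` etc.), so the quadratic law remains the
cohort mean curve while group contrasts equal the configured offsets
exactly; a residual sd of 0.3 cm^3 represents within-protocol
measurement and biological noise beyond age (the age law itself already
contributes an sd of about 0.73 cm^3 over this age span, so the total
spread lands near published cohort sds). Volumes truncate below at
0.5 cm^3.

Rater 2 re-measures rater 1 through a linear calibration
`v2 = 0.981 v1 + 0.156` plus calibration noise whose sd is *derived*,
not hard-coded: for an ordinary regression of rater 2 on rater 1,
`R^2 = slope^2 Var(v1) / (slope^2 Var(v1) + sigma_c^2)`, so the noise
that realizes a target R^2 = 0.93 is
`sigma_c = |slope| sd(v1) sqrt((1 - R^2)/R^2)`, with `Var(v1)` computed
in closed form from the uniform-age moments plus the offset and residual
variances (`calibration_noise_sd`). Non-volume descriptors are drawn
around their published cohort means; the diameter scales with the cube
root of each record's volume (geometric similarity), which is what makes
the low-volume probe find diameters of small hippocampi left of the
distribution mean while unlinked descriptors sit at the 50th percentile.

## Statistics

The cohort module wraps base R's fitting machinery rather than
reimplementing it: `lm` for the quadratic age fits (with reciprocal-
absolute-residual or 5-year-bin-mean weights; the literal
residuals-as-weights reading, which up-weights outliers, is kept as
`wls_raw_residual` for fidelity experiments), `t.test` for raw
comparisons, a closed-form Welch/Student path for published summary
statistics, and `ks.test` against a normal reference. Two caveats are
surfaced in the interfaces: with sample-estimated parameters the
one-sample KS p-value is conservative (the Lilliefors effect), so
`ks_normality` accepts known reference parameters when calibration
matters; and no multiple-testing adjustment is applied anywhere, matching
the descriptive character of the reports (flagged in every group
summary). Hemisphere comparisons treat left and right measurements as
independent samples by default, with a paired variant available.

Inter-rater agreement uses the pairwise-mean mismatch
`|m1 - m2| / ((m1 + m2)/2) * 100`, validated against four independently
published rater comparisons; match rates round to whole percent
(25 of 126 pairs reads as 20%). The tuning loop is deliberately a
book-keeping protocol with a pluggable revision callback, because the
real revision step is two specialists re-examining traces; its audit
trail (round 0 = untouched baseline) is what a study would archive.

# Problem sizes and determinism

The validation suite runs phantoms at 0.5 mm spacing (grids of roughly
45^3 to 96^3 voxels), cohort simulations at n = 63 to 2000 patients, 200
replicates for the hemisphere-test power check, and 500 replicates for
KS calibration; the full suite completes in a few minutes on one core.
The reconstruction and morphometry modules are deterministic for fixed
inputs (the only randomness, the miniball shuffle, uses a fixed seed);
phantom noise and cohort draws take the R RNG and restore its state
afterwards, so a seeded call is exactly reproducible and leaves the
session's stream untouched.
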