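---
title: "Methods: digital veneer design and fit assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital veneer design and fit assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After tooth autotransplantation, a premolar moved into an incisor site must
be restored to incisor shape, but definitive reshaping is delayed for
months to protect healing. The interim solution modelled here is a thin
printed veneer: the contralateral incisor crown is mirrored, placed over
the transplanted premolar, and the premolar is subtracted from it; the
subtraction solid, after finishing, is the print-ready veneer. Whether the
veneer fits is judged by two quantities: the *marginal gap* (distance
between veneer edge and tooth at the margin, measured on calibrated
microscope-style images; values near or below ~120 um are conventionally
acceptable, with 200 um used as the working cutoff) and *internal
adaptation* (the 3D thickness of the cement space between intaglio and
tooth, mapped from micro-CT).

veneerfit implements the whole chain — semi-interactive tooth
segmentation, veneer CAD, both fit protocols, and the statistics — plus a
synthetic phantom generator so that every stage can be tested with known
ground truth and no scanner data.

## Segmentation

Tooth segmentation follows the livewire paradigm. Slices are preprocessed
with an intensity window (piecewise-linear clamp; the bounds are
configuration, not constants) and a cubic median filter with replicate
padding. The pixel graph is weighted by `c = 1 - g / g_max` with `g` the
central-difference gradient magnitude, so strong edges are cheap; a
constant slice degrades to uniform cost 1 rather than erroring. Minimal
paths are computed by the F* raster-scan dynamic program: forward and
backward sweeps over the 8-connected grid, iterated to convergence, which
is cost-equivalent to Dijkstra (a property the test suite enforces against
an independent Dijkstra oracle). A step between two pixels costs the mean
of their costs times the geometric step length; the mean (rather than the
destination-only cost) makes the accumulated cost invariant under endpoint
reversal, so reversed anchor lists reproduce the same contour.

Closed contours on at least two orthogonal slice planes feed a variational
implicit-surface interpolation: on-surface constraints (value 0) at the
contour points, off-surface constraints (value -1) displaced inward along
the 2D contour normals by one voxel. The interpolant is the triharmonic
radial basis `|r|^3` plus a linear polynomial, solved densely (constraint
counts here are at most a few thousand; duplicates are removed before
solving). The function is negative inside; rasterization tests the sign at
voxel centers, and meshes are extracted by marching tetrahedra on the
Gaussian-smoothed indicator (sigma 1 voxel by default — raw binary
iso-surfaces overestimate area by roughly 25%, smoothing brings both area
and volume within a few percent on analytic solids).

## Geometry engine

No exact-arithmetic CSG kernel is available in the target environment, so
all mesh Booleans use a voxel-remesh kernel, the documented fallback of
dental CAD pipelines: watertight inputs are pre-cleaned (duplicate
vertices welded, degenerate faces dropped), rasterized on a shared grid by
parity ray casting, combined with mask logic, and re-triangulated by
marching tetrahedra (Freudenthal 6-tetrahedra decomposition with welded
edge vertices, so closed level sets give watertight, consistently oriented
meshes). The pitch defaults to `max extent / 220`, clamped to
`[0.02, 0.25]` mm, and is attached to every result as attribute `"pitch"`.
Two numerical choices matter:

* Grid origins carry a fixed irrational sub-voxel offset (0.2649618 of a
  pitch). Re-voxelizing a mesh that was itself produced on a grid of the
  same pitch would otherwise send parity rays within machine epsilon of
  mesh edges and corrupt the fill.
* Where sub-voxel surface placement matters (bevel chamfer, blockout
  envelope, phantom offset surfaces), fields are signed distances with
  exact point-to-mesh distances in a narrow band around the level set,
  not center-to-center voxel EDTs, which carry up to half-voxel phase
  bias on axis-aligned faces.

Accuracy on analytic solids at default pitches: Boolean volume
conservation `vol(A\B) + vol(A^B) = vol(A)` to ~0.01%, sphere–sphere lens
volume to ~0.1%, hemisphere cut to ~0.7%.

## Veneer design

`design_veneer()` runs the fixed finishing order: mirror (optional),
cervical crown isolation (half-space Boolean with capped cross-section),
placement, subtraction, undercut removal, edge bevel, thickness
inspection.

*Placement.* The study positions the crown manually under medium
transparency; the package replaces this with a centroid + principal-axes
initializer (long axis to long axis, deterministic sign convention) and an
explicit-transform override. The achieved intersection volume over crown
volume is attached to the transform as the objective surrogate
(`attr(tf, "overlap")`).

*Cement space.* The tooth is inflated by a `clearance` (default 0.12 mm;
clinical cement spacers run 30–150 um) before subtraction. This is both
clinically standard and numerically necessary: a veneer whose intaglio
coincides exactly with the tooth surface cannot satisfy
"intersection < 1e-3 x veneer volume" or a zero-interference seating sweep
under any finite-resolution Boolean, because the shared surface always
contributes a half-voxel skin.

*Undercut removal.* Blockout relative to the insertion axis (default
labial). The blocked region is the swept envelope of the tooth, dilated by
half the cement clearance, translated opposite the removal direction; on
the grid this is a running minimum of the tooth's signed distance field
along the axis. The veneer is trimmed to the complement, so material is
only removed. Seating is verified by a sweep test: 20 translated stations
over 2 mm, interference volume must be zero at every station.

*Bevel.* The margin band (default 0.3 mm at 45 degrees) is chamfered by a
per-slice lateral signed-distance constraint: at height `h` above the
margin plane, material within lateral depth `(band - h) * tan(angle)` of
the outer boundary is removed. Volume can only decrease and
watertightness is preserved.

*Thickness.* Wall thickness is measured by inward ray casting from sampled
surface vertices to the opposite wall (grid-accelerated, at most 2000
deterministic samples). Vertex normals are neighbor-smoothed first —
voxel-remeshed surfaces have staircase normals, and unsmoothed rays
overestimate shell thickness by ~10%. The default printing floor is
0.5 mm.

## Fit assessment

*Marginal protocol.* The stereomicroscope procedure is formalized as:
3-class intensity split of the margin image (background / veneer / tooth,
deterministic 1D k-means seeded at fixed quantiles), then at 6 evenly
spaced stations along the margin the shortest pixel distance from the
tooth edge to the veneer region, converted by the um-per-pixel
calibration. Six readings per image on cervical, mesial, and distal sides
give the study's 18 readings per veneer. "Shortest distance" is used
because the paper does not state whether readings were perpendicular or
absolute discrepancies; both aggregations (pooled and per-side) are
exposed because the paper does not say which fed the ANOVA.

*Internal adaptation.* The indirect micro-CT protocol: threshold the solid
phases, morphologically close with a ball of radius twice the expected gap
(so the closing bridges the radiolucent slit sandwiched between tooth and
veneer without merging distant structures), threshold the solid phases
again, and take the voxel-exact set difference `combined AND NOT enamel`.
Note the combined range must cover both solids: closing an enamel-only
mask is extensive but recovers the body, so a one-sided surface slit would
never be captured. The gap model keeps the largest connected component
(components under 10 voxels are noise), is meshed both ways (voxel count
and mesh Boolean, cross-checked in tests), and local thickness is the
inscribed-sphere diameter from the Euclidean distance transform with
sphere painting. Thickness is reported as `(d - 1) * spacing` where `d` is
the painted diameter in voxels measured center-to-center — this makes a
single-voxel gap read one voxel and recovers slab widths within one voxel.
Closing is computed on a grid padded by the closing radius; without the
padding the erosion bites inward from the volume boundary.

*Statistics.* Gap summaries use the sample SD (n-1) and type-7 quartiles;
`aggregate_per_sample_medians()` reproduces the "average median"
convention (median per sample, then mean/SD/IQR across samples; a single
sample reports SD 0 with a flag). One-way ANOVA is the classic
sums-of-squares F with the upper-tail p; it is tested against brute-force
sums of squares (1e-10 relative) and the two-group `F = t^2` identity.

## Phantoms: what they emulate and what they do not

Phantom teeth are parametric superellipsoid composites — a two-cusp crown
with a tapered root for premolars, a taller flattened-labial crown for
incisors — with a seeded smooth bumpiness field (default amplitude
0.05 mm). They exercise every geometric operator but are not anatomical:
no enamel/dentin distinction, no root canal, no realistic fissure
anatomy. A green test therefore establishes correctness of the
*operators*, not clinical accuracy on real dentitions.

`make_seated_pair()` builds the seated veneer exactly: the intaglio is the
tooth surface offset outward by the realized gap field (uniform, smooth
random with prescribed marginal mean/SD and correlation length, or
sinusoidal; truncated at zero), the outer surface is the placed incisor
crown, and the solid is clipped to the labial side so cervical, mesial and
distal margins exist. Intaglio vertices are snapped onto the exact offset
surface by closest-point projection — marching-tetrahedra interpolation
alone leaves ~5 um errors in high-curvature fissures, and the generator's
contract is a micrometre-exact ground truth.

Scan emulation assigns phase intensities (enamel > resin > air, matching
micro-CT radiodensity ordering), Gaussian blur as a partial-volume
surrogate, and additive Gaussian noise; there is no beam hardening, ring
artefact, or Poisson physics (reconstruction-side corrections are out of
scope; a radial bias hook can be added to the intensity map for robustness
experiments). Margin images are drawn from the geometrically measured gap
profile at intaglio-edge stations — an idealized two-phase rendering of
what the microscope sees, with the true profile attached as ground truth.

Default batch conditions mirror the study: 15 veneers, gap field mean
100 um and SD 50 um truncated at zero, 6 readings per image on 3 sides,
200 um cutoff, CBCT-like 0.2 mm and micro-CT-like 12.8 um voxels.

## Scale choices under the test budget

A full seated-crown scene at 12.8 um voxels is ~1500^3 voxels and does not
fit a 1-CPU/8-GiB budget. The micro-CT end-to-end test therefore runs on a
cropped labial window (~2 x 1 x 1 mm) at true spacing — the study likewise
scans only the seated crown region. Slab/shell thickness recovery runs at
full 12.8 um spacing. Design-stage Booleans default to 0.07–0.09 mm pitch
in tests; accuracy statements above were verified to hold at those
pitches.

## Known limitations

* Booleans are resolution-limited; sharp creases are rounded at the pitch
  scale. The pitch is always recorded on results.
* `compute_thickness_map()` requires near-isotropic spacing (true of both
  emulated modalities).
* The DICOM reader covers explicit-VR little-endian single-frame
  grayscale series — the subset clinical CBCT exports use — and rejects
  anything else with a metadata error rather than guessing.
* Configuration files are JSON (the environment provides jsonlite; no
  YAML parser is available).
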