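---
title: "From CAD meshes to FLUKA voxel models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CAD meshes to FLUKA voxel models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flukavox)
```

## Why voxelize

FLUKA describes geometry as Boolean combinations of a fixed catalogue of
primitive bodies.  Shapes that are not expressible in that catalogue — a
torus, a ripple filter with hundreds of sub-millimetre ridges, any free-form
printed part — have to enter through the voxel route: a regular lattice of
material labels imported via a `VOXELS` card.  `flukavox` turns a watertight
STL surface into such a lattice and quantifies how faithful the conversion
is, using the three-way comparison standard in this setting: the closed-form
volume of the ideal solid, the enclosed volume of its tessellation, and the
voxel-model volume (entity-voxel count × voxel volume).

## The voxelization procedure

A voxel is labelled *entity* exactly when its **centre** lies inside the
solid.  Centre sampling matches the binary entity/empty matrix semantics of
the downstream format and keeps the rule deterministic and unbiased for
surfaces that are flat at the voxel scale: along any axis the occupied span
snaps to the nearest half-voxel, so signed surface errors largely cancel.
The alternative — any-overlap occupancy — systematically dilates the solid
by up to half a voxel per face and was rejected.

The inside test is evaluated slice by slice.  For the plane through the
z-centres of one voxel layer, every triangle spanning the plane is
intersected with it, giving a set of 2D segments that together form the
closed cross-section contour.  Occupancy along each row of voxel centres
then follows from even–odd crossing parity.  Two robustness rules matter:

* **Slice-plane ties.**  If a plane passes within `1e-7·dz` of any mesh
  vertex z-coordinate, the plane (not the mesh) is nudged by `+1e-7·dz`.
  This keeps results deterministic — no random jitter — while guaranteeing
  that no vertex ever sits exactly on a slicing plane.
* **Row ties.**  Each segment contributes crossings to rows with centres in
  the half-open interval `[ymin, ymax)`, with a `1e-7`-of-a-voxel snap so
  that two segments sharing an endpoint (up to floating-point round-off)
  classify a row centre that coincides with that endpoint identically.
  Without the snap, the two collinear sub-segments a triangulated wall
  produces can disagree about a shared endpoint by one ulp and leave a row
  with an odd crossing count.

An odd crossing count that survives these rules indicates a genuinely open
contour; `voxelize()` then fails loudly, naming the slice, rather than
producing a silently wrong grid.  `slice_mesh_at_plane()` exposes the same
sectioning as explicit closed polygons (chained by endpoint matching) for
inspection and testing.

**Lattice convention.**  `voxel_size = extent / resolution` per axis, and
the lattice covers the mesh bounding box expanded by `pad_voxels` (default
1) empty voxels on every face, because a FLUKA voxel structure needs an
embedding layer of the ambient material.  Published voxel sizes from other
conversion chains imply padding rules that differ from shape to shape; this
package fixes one documented convention and exposes `pad_voxels` so either
behaviour can be approximated.  Resolutions are per-axis: extruded plates
such as the ripple filter are meaningfully voxelized at 1000×10×1000 —
fine across the ridges and through the height, coarse along the extrusion
axis where nothing varies.

## Test geometries and tessellation control

The shape factory generates the standard validation set — cube (100 mm
edge), sphere (r = 50 mm), cone (r = 50 mm, h = 100 mm), torus — plus two
beam modulators: the 1D ripple filter (0.3 mm base, triangular prism
ridges of 1 mm period and 2.4 mm height, 60 periods, 60 mm long) and a
stepped ridge-filter bar array.  The ridges are prisms, not point pyramids:
the device is one-dimensional by name and by use, and only an extrusion is
compatible with a deliberately coarse resolution along one axis.  The ridge
filter's true 21-step bar profile is proprietary to its design process;
the default here is a *synthetic* stand-in (widths falling linearly
4.8→0.2 mm, heights proportional to step index, summing to the known
10.4 mm cumulative height) and the profile is an ordinary input, so a user
with a real design supplies their own `(width, height)` pairs.

Curved surfaces are tessellated under two CAD-style export controls:
maximum surface deviation (chord sag, default 0.1 mm) and maximum
adjacent-facet normal angle (default 30°).  Segment counts are the smallest
satisfying both.  One subtlety: on a *doubly*-curved surface (sphere,
torus) the worst deviation occurs in the facet interior and is close to the
sum of the two per-direction chord sags, so those surfaces budget half the
sag allowance per direction.  With the defaults this gives the sphere 71
azimuthal segments (the single-direction bound alone would give 50, and a
volume deficit well above the tolerance the conversion is expected to
meet).  All generated solids are watertight by construction — verified by
an edge census after vertex welding — and wound outward, with a signed
volume check flipping any inverted construction.

Tessellations are inscribed, so mesh volumes *underestimate* the smooth
solid: with the default controls the deficit is ≈0.32% for the sphere and
≈0.26% for the cone, and the deficit falls roughly linearly in the sag
allowance.  The voxelizer, in turn, converges to the volume of the mesh it
is given, not of the ideal solid; at coarse resolutions its (positive)
sampling error can partially cancel the mesh deficit, which is why
convergence is monitored against the mesh volume while the accuracy bound
is stated against the analytic volume.

## Dose-side validation

The geometric half of a conversion check is volumes; the dosimetric half
compares dose distributions scored behind the converted and the reference
geometry.  The package implements the analysis tools; it does not do
particle transport.

**Gamma index.**  `gamma_map()` computes, per reference point above a
low-dose threshold (default 10% of the global maximum),
`γ = min over nearby evaluated points of sqrt(ΔD²/(dose%·D_max)² + Δx²/DTA²)`
with *global* normalization (D_max is the reference grid maximum).  The
minimization searches a sphere of radius `search_factor·DTA` (default 3)
over the evaluated grid refined by trilinear interpolation (default factor
3), which mitigates the discretization bias of comparing 0.5 mm grids
under a 1 mm DTA.  Offsets are visited in order of increasing distance, so
the search stops as soon as the distance term alone exceeds the worst
current γ².  Points whose true minimizer lies outside the sphere are
reported at the capped minimum — they are far above γ = 1 either way.  The
threshold mask applies to the reference grid, the conventional choice.
Local-normalization modes are intentionally out of scope.

**Depth-dose metrics.**  `idd_metrics()` reads R80, R20, DFW and BPW off a
curve using linear interpolation between the bracketing samples; the
distal crossing is the *deepest* downward crossing, which makes the
definition stable when noise creates multiple crossings.  The 100% level
is the unsmoothed global maximum — determinism first; an optional smoothing
window would trade that for noise robustness and is deliberately not a
default.  In `point_to_point_deviation()` the quoted pair follows the
"mean ± SD" convention in which the mean is of *absolute* deviations while
the SD is of *signed* ones — the only reading under which a mean below its
SD is coherent.

**Fixtures.**  `bragg_spec()`/`make_bragg_curve()` provide an analytic
depth-dose stand-in: an entrance plateau rising through a Gaussian shoulder
to the peak (optionally held flat over a modulation width for an SOBP) and
a Gaussian distal falloff placed so the distal 80% level sits exactly at
the requested R80.  Every crossing depth has a closed form, so the metric
extractors are tested against root-finding on the generator itself — an
oracle independent of the sampled-curve code path.  This is *not* a
physical Bragg model: no stopping-power physics, no nuclear build-up, no
energy straggling.  Passing tests on these fixtures shows the metrics and
the gamma machinery are computed correctly, not that any particular
transport result is reproduced; transport-dependent figures (gamma passing
rates behind real modulators, IDD deviations between converted and
reference geometry) require a Monte Carlo run and are explicitly outside
what this package can validate on its own.

## Numerical and interface choices

* Mesh coordinates are mm (STL carries no units; mm is the de-facto CAD
  convention); volumes are reported in cm³; the voxel exchange file is in
  cm because that is FLUKA's native unit.
* STL format auto-detection: a file is binary when the 80-byte-header
  record-count size check passes, or when it has a full header and does not
  begin with `solid` — real binary exporters often start the header with
  `solid`, so the prefix alone is not trusted.
* Binary STL stores float32; the default weld tolerance for the
  watertightness census is `1e-6` mm to match.  Degenerate (zero-area)
  triangles are kept on read but excluded from the edge census.
* The voxel text layout (counts / sizes / material count / labels
  x-fastest) is this package's documented contract for a matching
  `writegolem.f` variant: the order matches Fortran's default array fill.
  No claim of bit-compatibility with any private routine is made.
* Writing streams one z-slice at a time; memory stays constant beyond a
  slice for arbitrarily large grids.

## Problem sizes

The validation suite voxelizes the three basic solids at 400 voxels per
axis and the two modulator plates at 1000×10×1000 — the full study
resolutions, about 6.4×10⁷ lattice cells for the cube — in roughly 10 s
per solid in pure R, thanks to the slice-vectorized parity fill.
Oracle-equivalence checks (brute-force ray casting per voxel centre,
exhaustive gamma minimization) run at reduced sizes — 16³ grids and ≤20-mm
dose fields — chosen so the exhaustive reference itself stays exact and
fast; the equivalence they establish is resolution-independent because
both code paths implement the same pointwise definitions.

## Known limitations

* Meshes must be watertight; there is no repair, decimation or Boolean
  CSG.  Non-manifold input fails the edge census and is rejected.
* Only binary occupancy is produced (labels 0/1).  The containers and the
  text format already carry arbitrary small integer labels for
  multi-material work, but no multi-material assignment logic exists yet.
* No anti-aliasing / partial-volume occupancy: a voxel is in or out.
* The gamma implementation is methodologically standard but is not a
  clone of any commercial tool; agreement with numbers produced by such
  tools on transported dose cannot be claimed, only equivalence of
  definition.
* The Bragg fixtures are analytic conveniences, not beam models.
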