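# flukavox

Voxelization of CAD triangle meshes into FLUKA-ready voxel geometry models
(VGMs), with the validation toolkit used to qualify such conversions.

## The problem

FLUKA, a general-purpose Monte Carlo particle-transport code widely used in
particle-beam radiotherapy, builds geometry from a fixed set of primitive
bodies combined with Boolean operations.  It cannot *create* new surface
types, so shapes outside its primitive catalogue (a torus, a 3D-printed
ripple filter, a patient-specific bolus) cannot be modelled directly.  CAD
tools, on the other hand, export almost any solid as an STL triangle mesh.
The bridge is voxelization: convert the watertight mesh into a regular
lattice of "entity"/"empty" labels (a binary 3D matrix), write it in a text
format a `writegolem.f` user routine can compile into a FLUKA voxel
structure, and import it with a `VOXELS` card.

`flukavox` implements that bridge end to end, plus the quantitative checks
a medical physicist runs before trusting the converted geometry:

* **mesh_io** — binary/ASCII STL reading and writing, watertightness
  census, axis-aligned bounds, and the divergence-theorem enclosed volume
  `V = |Σ det(v0, v1, v2)| / 6` over all triangles.
* **shape factory** — parametric, watertight test solids: cube, sphere,
  cone, torus, a one-dimensional ripple filter (1D-RiFi: 0.3 mm base plus
  triangular prism ridges of 1 mm period and 2.4 mm height) and a stepped
  ridge filter (RGF), tessellated so that surface sag and adjacent-facet
  normal angle stay within user bounds (defaults 0.1 mm and 30°).
* **voxelizer** — slice-plane polygonization with even-odd scanline fill at
  voxel centres, independent per-axis resolutions (e.g. 400×400×400, or
  1000×10×1000 for extruded plates), voxel-model volumes and signed
  deviations `(V_test − V_ref)/V_ref`.
* **fluka_io** — the plain-text voxel exchange format (counts, sizes in
  cm, material count, labels x-fastest in Fortran fill order) and the
  `VOXELS` card snippet with fixed 10-character fields.
* **dose metrics & gamma index** — R80 (distal 80% range), DFW (80→20%
  distal falloff width), BPW (proximal-to-distal 80% peak width), SOBP
  width (90→90%), point-to-point deviation statistics, IDD extraction over
  a circular detection region, and a 3D gamma index
  `γ(r) = min_e sqrt(ΔD²/(dose%·D_max)² + Δx²/DTA²)` with global
  normalization, low-dose threshold and trilinear sub-sampling.
* **analytic fixtures** — a documented closed-form Bragg-curve stand-in
  and separable 3D dose fields, so every dose metric is testable against
  an independent oracle without running particle transport.

## Worked example

Volumes of the three basic solids, tessellated at 0.1 mm sag / 30° and
voxelized at 400 voxels per axis:

```r
flukavox::vgm_cli(c("volume-report", "--shapes", "cube,sphere,cone", "--quiet"))
```

```
  shape voxel_vol_mm3 voxel_number analytic_cm3 mesh_cm3 vgm_cm3 mesh_dev vgm_dev
   cube       0.01562     64000000      1000.00  1000.00 1000.00   +0.00%  +0.00%
 sphere       0.01561     33427332       523.60   521.92  521.92   -0.32%  -0.32%
   cone       0.01559     16744504       261.80   261.11  261.12   -0.26%  -0.26%
```

Reading the table: `analytic_cm3` is the closed-form volume of the smooth
solid (a³, 4πr³/3, πr²h/3), `mesh_cm3` the divergence-theorem volume of the
inscribed tessellation (always a slight underestimate for convex solids),
and `vgm_cm3` the entity-voxel count times the voxel volume.  The cube is
exact by construction; the curved solids lose ~0.3% to the inscribed
tessellation, while the voxelization itself adds well under 0.1%.

The same pipeline from the shell (via the thin launcher in `inst/cli/`):

```sh
Rscript inst/cli/vgmtool.R make-shape --kind sphere --radius 50 --out sphere.stl
Rscript inst/cli/vgmtool.R voxelize --in sphere.stl --res 400,400,400 --out sphere_vox.txt
Rscript inst/cli/vgmtool.R export-fluka --in sphere_vox.txt --out sphere_voxels.inp
```

and a gamma comparison of two scored dose grids:

```sh
Rscript inst/cli/vgmtool.R gamma --ref dgm_dose.txt --eval vgm_dose.txt --crit 1,1 --threshold 10
```

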