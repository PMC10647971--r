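Package: flukavox
Title: Triangle-Mesh Voxelization and Validation for FLUKA Voxel Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts watertight STL triangle meshes into regular voxel
    occupancy lattices suitable for import into the FLUKA Monte Carlo
    particle-transport code as voxel geometry models (VGMs).  Provides
    parametric generators for standard radiotherapy test geometries (cube,
    sphere, cone, torus, one-dimensional ripple filter, ridge filter) with
    tessellation bounded by maximum surface-sag and facet-angle deviation,
    per-axis voxelization resolutions, a plain-text voxel exchange format
    plus a VOXELS input-card snippet, and the validation toolkit used to
    qualify such conversions: divergence-theorem mesh volumes, voxel-model
    volume deviations, 3D gamma-index dose comparison with global
    normalization, and depth-dose metrics (R80, distal falloff width, Bragg
    peak width, SOBP width) with analytic Bragg-curve fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
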