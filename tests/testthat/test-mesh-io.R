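test_that("binary STL round trip preserves triangles at float32 precision", {
  for (kind in c("cube", "cone")) {
    mesh <- make_shape(coarse_spec(kind))
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(mesh, path, format = "binary")
    back <- read_stl(path)
    expect_equal(n_triangles(back), n_triangles(mesh))
    # float32 storage: relative error bounded by 2^-24 of the magnitude
    expect_lt(max(abs(back$vertices - mesh$vertices)),
              max(abs(mesh$vertices)) * 2^-23 + 1e-12)
  }
})

test_that("ASCII STL output conforms and round-trips within print precision", {
  mesh <- make_shape(coarse_spec("sphere"))
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, format = "ascii")
  lines <- readLines(path)
  expect_match(lines[1], "^solid sphere")
  expect_match(lines[length(lines)], "^endsolid sphere")
  back <- read_stl(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6)
})

test_that("a single-facet ASCII file parses to the stated triangle", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid one",
               "  facet normal 0 0 1",
               "    outer loop",
               "      vertex 0 0 0",
               "      vertex 1 0 0",
               "      vertex 0 1 0",
               "    endloop",
               "  endfacet",
               "endsolid one"), path)
  mesh <- read_stl(path)
  expect_equal(n_triangles(mesh), 1L)
  expect_equal(mesh$vertices, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  b <- mesh_bounds(mesh)
  expect_equal(unname(b$min), c(0, 0, 0))
  expect_equal(unname(b$max), c(1, 1, 0))
})

test_that("malformed STL files produce parse errors naming the location", {
  # truncated binary file
  mesh <- make_shape(coarse_spec("cube"))
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, format = "binary")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(raw[1:(length(raw) - 7L)], path)
  expect_error(read_stl(path), "byte offset")
  # malformed ASCII vertex token
  writeLines(c("solid bad", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 zero", "      vertex 1 0 0",
               "      vertex 0 1 0", "    endloop", "  endfacet",
               "endsolid bad"), path)
  expect_error(read_stl(path), "line 4")
})

test_that("a binary file whose header starts with 'solid' is still binary", {
  mesh <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        name = "solid-prefixed")
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, path, format = "binary")
  # header written by write_stl begins "flukavox ..."; force a "solid" prefix
  raw <- readBin(path, "raw", n = file.info(path)$size)
  raw[1:6] <- charToRaw("solid ")
  writeBin(raw, path)
  expect_equal(n_triangles(read_stl(path)), 1L)
})

test_that("mesh_volume matches closed forms and flags open meshes", {
  expect_equal(mesh_volume(unit_tetrahedron()), 1 / 6 / 1000,
               tolerance = 1e-12)
  cube <- make_shape(shape_spec("cube"))
  expect_equal(mesh_volume(cube), 1000, tolerance = 1e-9)
  # deleting a triangle opens the surface: warning and unreliable flag
  open_mesh <- triangle_mesh(cube$vertices[-(1:3), ], name = "open")
  expect_false(is_watertight(open_mesh))
  expect_warning(v <- mesh_volume(open_mesh), "not watertight")
  expect_true(isTRUE(attr(v, "unreliable")))
})

test_that("mesh_volume is invariant under rigid motion", {
  set.seed(42)
  mesh <- make_shape(coarse_spec("torus"))
  v0 <- mesh_volume(mesh, check = FALSE)
  for (rep in 1:5) {
    moved <- flukavox:::.transform_mesh(mesh, rotation = random_rotation(),
                                        translation = stats::rnorm(3, sd = 40))
    expect_lt(abs(mesh_volume(moved, check = FALSE) - v0) / v0, 1e-9)
  }
})

test_that("inscribed tessellations underestimate and converge under refinement", {
  va <- analytic_volume(shape_spec("sphere"))
  vols <- vapply(c(2, 0.5, 0.1), function(sag)
    mesh_volume(make_shape(shape_spec("sphere", max_surface_deviation = sag)),
                check = FALSE), numeric(1))
  expect_true(all(vols <= va))
  expect_true(all(diff(vols) > 0))        # deficit shrinks under refinement
})

test_that("watertightness census accepts all generated fixtures", {
  for (kind in c("cube", "sphere", "cone", "torus", "rifi1d", "rgf"))
    expect_true(is_watertight(make_shape(coarse_spec(kind))),
                label = paste("watertight", kind))
})

test_that("mesh constructors and writers reject invalid input", {
  expect_error(triangle_mesh(matrix(1, 4, 3)), "multiple of 3")
  expect_error(triangle_mesh(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0))),
               "finite")
  expect_error(triangle_mesh(matrix(numeric(0), 0, 3)), "multiple of 3")
  expect_error(write_stl(list(), tempfile()), class = "error")
})
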