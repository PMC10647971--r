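#' Construct a triangle mesh
#'
#' A `triangle_mesh` is a triangle soup: an ordered collection of vertex
#' triples in millimetres, stored as a single numeric matrix in which rows
#' `3i-2, 3i-1, 3i` are the three vertices of triangle `i`.  No topology is
#' stored; watertightness is a property checked on demand with
#' [is_watertight()].
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm) and a row
#'   count that is a multiple of 3; all coordinates must be finite.
#' @param name free-text solid name (written into STL output).
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `name`.
#' @seealso [read_stl()], [write_stl()], [mesh_volume()]
#' @export
triangle_mesh <- function(vertices, name = "mesh") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (x, y, z)")
  if (nrow(vertices) < 3L || nrow(vertices) %% 3L != 0L)
    stop("'vertices' row count must be a positive multiple of 3")
  if (!all(is.finite(vertices)))
    stop("all mesh coordinates must be finite")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, name = as.character(name)[1]),
            class = "triangle_mesh")
}

#' Number of triangles in a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer triangle count.
#' @export
n_triangles <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nrow(mesh$vertices) %/% 3L
}

#' @export
print.triangle_mesh <- function(x, ...) {
  b <- mesh_bounds(x)
  cat(sprintf("triangle_mesh '%s': %d triangles\n", x$name, n_triangles(x)))
  cat(sprintf("  bounds (mm): [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
              b$min[1], b$max[1], b$min[2], b$max[2], b$min[3], b$max[3]))
  invisible(x)
}

# per-triangle vertex row indices
.tri_rows <- function(mesh) {
  nt <- n_triangles(mesh)
  list(a = seq(1L, by = 3L, length.out = nt),
       b = seq(2L, by = 3L, length.out = nt),
       c = seq(3L, by = 3L, length.out = nt))
}

# unit outward normals from counter-clockwise winding
.tri_normals <- function(mesh) {
  V <- mesh$vertices
  r <- .tri_rows(mesh)
  e1 <- V[r$b, , drop = FALSE] - V[r$a, , drop = FALSE]
  e2 <- V[r$c, , drop = FALSE] - V[r$a, , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1      # degenerate triangle: emit zero normal
  n / len
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return an object of class `aabb`: list with `min` and `max` 3-vectors (mm).
#' @export
mesh_bounds <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices
  structure(list(min = apply(V, 2, min), max = apply(V, 2, max)),
            class = "aabb")
}

#' @export
print.aabb <- function(x, ...) {
  cat(sprintf("aabb (mm): min (%g, %g, %g)  max (%g, %g, %g)\n",
              x$min[1], x$min[2], x$min[3], x$max[1], x$max[2], x$max[3]))
  invisible(x)
}

# Weld vertices within tolerance; returns integer vertex ids per mesh row.
.weld_ids <- function(V, weld_tol) {
  if (weld_tol <= 0) weld_tol <- .Machine$double.eps
  key <- paste(round(V[, 1] / weld_tol), round(V[, 2] / weld_tol),
               round(V[, 3] / weld_tol))
  match(key, unique(key))
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight (a closed 2-manifold) when, after welding vertices
#' that coincide within `weld_tol`, every undirected edge is shared by
#' exactly two triangles.  Degenerate (zero-area) triangles are tolerated on
#' read but excluded from the edge census.
#'
#' @param mesh a [triangle_mesh()].
#' @param weld_tol welding tolerance in mm; the default suits float32 STL
#'   storage.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh, weld_tol = 1e-6) {
  stopifnot(inherits(mesh, "triangle_mesh"), weld_tol >= 0)
  ids <- .weld_ids(mesh$vertices, weld_tol)
  r <- .tri_rows(mesh)
  a <- ids[r$a]; b <- ids[r$b]; c <- ids[r$c]
  ok <- a != b & b != c & a != c      # drop collapsed triangles
  a <- a[ok]; b <- b[ok]; c <- c[ok]
  if (!length(a)) return(FALSE)
  e1 <- cbind(pmin(a, b), pmax(a, b))
  e2 <- cbind(pmin(b, c), pmax(b, c))
  e3 <- cbind(pmin(c, a), pmax(c, a))
  edges <- rbind(e1, e2, e3)
  key <- paste(edges[, 1], edges[, 2])
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes
#' `det(v0, v1, v2) / 6` over all triangles, taken relative to the origin.
#' The absolute value of the sum is returned, so a globally reversed winding
#' still yields the correct magnitude.  Coordinates are mm; the result is
#' converted to cm^3.
#'
#' @param mesh a [triangle_mesh()]; should be watertight with consistent
#'   orientation.
#' @param check if `TRUE` (default), run [is_watertight()] first and warn on
#'   failure; the returned value then carries attribute `unreliable = TRUE`.
#' @return volume in cm^3 (numeric scalar).
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices
  r <- .tri_rows(mesh)
  A <- V[r$a, , drop = FALSE]
  B <- V[r$b, , drop = FALSE]
  C <- V[r$c, , drop = FALSE]
  # scalar triple product A . (B x C)
  det6 <- A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) +
          A[, 2] * (B[, 3] * C[, 1] - B[, 1] * C[, 3]) +
          A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])
  vol <- abs(sum(det6) / 6) / 1000     # mm^3 -> cm^3
  if (check && !is_watertight(mesh)) {
    warning("mesh is not watertight; volume is unreliable")
    attr(vol, "unreliable") <- TRUE
  }
  vol
}

#' Read an STL file
#'
#' Both binary and ASCII STL dialects are supported; the format is
#' auto-detected.  A file that begins with `solid` but whose size matches the
#' binary record layout (80-byte header + uint32 count + 50-byte records) is
#' treated as binary, since real-world binary exporters often start the
#' header with `solid`.  STL carries no unit metadata; coordinates are taken
#' as millimetres.
#'
#' @param path file path.
#' @return a [triangle_mesh()] with triangles in file order.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(84, size))
  starts_solid <- length(head) >= 5 &&
    identical(head[1:5], charToRaw("solid"))
  is_binary <- FALSE
  if (length(head) >= 84) {
    count <- readBin(head[81:84], "integer", size = 4, endian = "little")
    # a file starting with "solid" is binary only when the record-count
    # size check confirms it; anything else with a full header is binary
    if (count >= 0 && size == 84 + 50 * as.numeric(count)) is_binary <- TRUE
    else if (!starts_solid) is_binary <- TRUE
  }
  if (is_binary) .read_stl_binary(con, head, size, path)
  else .read_stl_ascii(path)
}

.read_stl_binary <- function(con, head, size, path) {
  count <- readBin(head[81:84], "integer", size = 4, endian = "little")
  body <- readBin(con, "raw", n = size - 84)
  if (length(body) != 50 * count)
    stop(sprintf("truncated binary STL '%s': expected %d record bytes, found %d (at byte offset %d)",
                 path, 50 * count, length(body), 84 + length(body)))
  # each 50-byte record: 12 float32 (normal + 3 vertices) then uint16 attr
  rec0 <- seq(0L, by = 50L, length.out = count)
  fidx <- rep(rec0, each = 48L) + seq_len(48L)
  floats <- readBin(body[fidx], "double", size = 4, n = 12L * count,
                    endian = "little")
  m <- matrix(floats, nrow = 12L)            # one record per column
  verts <- matrix(0, nrow = 3L * count, ncol = 3L)
  verts[seq(1L, by = 3L, length.out = count), ] <- t(m[4:6, , drop = FALSE])
  verts[seq(2L, by = 3L, length.out = count), ] <- t(m[7:9, , drop = FALSE])
  verts[seq(3L, by = 3L, length.out = count), ] <- t(m[10:12, , drop = FALSE])
  name <- rawToChar(head[1:80][head[1:80] != as.raw(0)])
  name <- sub("^solid\\s*", "", trimws(name))
  if (!nzchar(name)) name <- "mesh"
  triangle_mesh(verts, name = name)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- trimws(lines[1])
  if (!startsWith(first, "solid"))
    stop(sprintf("malformed ASCII STL '%s': line 1 does not start with 'solid'", path))
  name <- trimws(sub("^solid", "", first))
  if (!nzchar(name)) name <- "mesh"
  vi <- grep("^\\s*vertex\\b", lines)
  if (length(vi) == 0L || length(vi) %% 3L != 0L)
    stop(sprintf("malformed ASCII STL '%s': vertex count %d is not a positive multiple of 3",
                 path, length(vi)))
  toks <- strsplit(trimws(lines[vi]), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad))
    stop(sprintf("malformed ASCII STL '%s': bad vertex token at line %d",
                 path, vi[bad[1]]))
  num <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(num)) {
    bad <- which(colSums(is.na(num)) > 0)[1]
    stop(sprintf("malformed ASCII STL '%s': non-numeric vertex at line %d",
                 path, vi[bad]))
  }
  triangle_mesh(t(num), name = name)
}

#' Write an STL file
#'
#' Binary output stores vertices as little-endian float32 (bit-exact round
#' trip through [read_stl()] at float32 precision); ASCII output prints 9
#' significant digits.  Facet normals are recomputed as unit cross products
#' assuming counter-clockwise-outward winding.
#'
#' @param mesh a non-empty [triangle_mesh()].
#' @param path output file path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  nt <- n_triangles(mesh)
  if (nt < 1L) stop("refusing to write an empty mesh")
  N <- .tri_normals(mesh)
  V <- mesh$vertices
  r <- .tri_rows(mesh)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("flukavox", mesh$name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    m <- rbind(t(N), t(V[r$a, , drop = FALSE]), t(V[r$b, , drop = FALSE]),
               t(V[r$c, , drop = FALSE]))      # 12 floats per column/record
    fraw <- writeBin(as.vector(m), raw(), size = 4, endian = "little")
    recs <- matrix(as.raw(0), nrow = 50L, ncol = nt)
    recs[1:48, ] <- matrix(fraw, nrow = 48L)
    writeBin(as.vector(recs), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    f <- function(x) sprintf("%.9g", x)
    lines <- character(7L * nt + 2L)
    lines[1] <- paste("solid", mesh$name)
    idx <- 7L * (seq_len(nt) - 1L) + 1L
    lines[idx + 1L] <- sprintf("  facet normal %s %s %s",
                               f(N[, 1]), f(N[, 2]), f(N[, 3]))
    lines[idx + 2L] <- "    outer loop"
    va <- V[r$a, , drop = FALSE]; vb <- V[r$b, , drop = FALSE]
    vc <- V[r$c, , drop = FALSE]
    lines[idx + 3L] <- sprintf("      vertex %s %s %s", f(va[, 1]), f(va[, 2]), f(va[, 3]))
    lines[idx + 4L] <- sprintf("      vertex %s %s %s", f(vb[, 1]), f(vb[, 2]), f(vb[, 3]))
    lines[idx + 5L] <- sprintf("      vertex %s %s %s", f(vc[, 1]), f(vc[, 2]), f(vc[, 3]))
    lines[idx + 6L] <- "    endloop"
    lines[idx + 7L] <- "  endfacet"
    lines[7L * nt + 2L] <- paste("endsolid", mesh$name)
    writeLines(lines, con)
  }
  invisible(path)
}

# Rigid motion helper used by tests and the shape factory.
.transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  triangle_mesh(mesh$vertices %*% t(rotation) +
                  matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE),
                name = mesh$name)
}

#' Translate a mesh
#' @param mesh a [triangle_mesh()].
#' @param offset 3-vector in mm.
#' @return translated [triangle_mesh()].
#' @export
translate_mesh <- function(mesh, offset) {
  stopifnot(length(offset) == 3, all(is.finite(offset)))
  .transform_mesh(mesh, translation = offset)
}
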