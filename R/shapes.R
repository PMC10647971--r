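#' Parametric test-geometry specification
#'
#' Describes one of the standard beam-line test solids as a parametric shape
#' with tessellation control.  Curved surfaces are tessellated with the
#' smallest segment counts satisfying both a chord-sag bound
#' (`max_surface_deviation`, mm) and an adjacent-facet normal-angle bound
#' (`max_angle_deviation`, degrees), the two export controls a CAD tool
#' exposes when writing STL.
#'
#' Supported kinds and their parameters (all mm):
#' \describe{
#'   \item{cube}{`edge` (default 100).}
#'   \item{sphere}{`radius` (default 50).}
#'   \item{cone}{`radius` (default 50), `height` (default 100).}
#'   \item{torus}{`major_radius` (default 30), `minor_radius` (default 10).}
#'   \item{rifi1d}{one-dimensional ripple filter: `base` thickness (0.3),
#'     ridge `period` (1), ridge `height` (2.4), `n_periods` (60), lateral
#'     `length` along the extrusion axis (60).  Triangular prism ridges are
#'     extruded along y, so the plate is fine-structured in x and z only.}
#'   \item{rgf}{ridge filter: `widths` and `heights` — equal-length vectors
#'     describing the stepped bar cross-section from bottom to top (step i is
#'     a cuboid `widths[i]` wide and `heights[i]` tall), `bar_length` along
#'     y (60), `n_bars` (12), `pitch` bar spacing (5).  The default profile
#'     is synthetic: 21 steps with widths decreasing 4.8 to 0.2 mm and
#'     heights proportional to step index summing to 10.4 mm.}
#' }
#'
#' @param kind shape kind, see Details.
#' @param ... kind-specific dimensional parameters overriding the defaults.
#' @param max_surface_deviation maximum chord sag of the tessellation, mm.
#' @param max_angle_deviation maximum angle between adjacent facet normals on
#'   a curved surface, degrees (0 < value <= 90).
#' @return an object of class `shape_spec`.
#' @seealso [make_shape()], [analytic_volume()]
#' @export
shape_spec <- function(kind = c("cube", "sphere", "cone", "torus", "rifi1d", "rgf"),
                       ..., max_surface_deviation = 0.1,
                       max_angle_deviation = 30) {
  kind <- match.arg(kind)
  if (!is.numeric(max_surface_deviation) || max_surface_deviation <= 0)
    stop("invalid shape_spec field 'max_surface_deviation': must be > 0")
  if (!is.numeric(max_angle_deviation) || max_angle_deviation <= 0 ||
      max_angle_deviation > 90)
    stop("invalid shape_spec field 'max_angle_deviation': must be in (0, 90]")
  defaults <- switch(kind,
    cube   = list(edge = 100),
    sphere = list(radius = 50),
    cone   = list(radius = 50, height = 100),
    torus  = list(major_radius = 30, minor_radius = 10),
    rifi1d = list(base = 0.3, period = 1, height = 2.4, n_periods = 60L,
                  length = 60),
    rgf    = {
      h <- 10.4 * (1:21) / sum(1:21)
      list(widths = seq(4.8, 0.2, length.out = 21), heights = h,
           bar_length = 60, n_bars = 12L, pitch = 5)
    })
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("invalid shape_spec field(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  par <- utils::modifyList(defaults, dots)
  for (nm in setdiff(names(par), c("widths", "heights"))) {
    if (!is.numeric(par[[nm]]) || length(par[[nm]]) != 1 || par[[nm]] <= 0)
      stop("invalid shape_spec field '", nm, "': must be a positive scalar")
  }
  if (kind == "rgf") {
    w <- par$widths; h <- par$heights
    if (length(w) != length(h) || length(w) < 1)
      stop("invalid shape_spec field 'widths'/'heights': lengths must match")
    if (any(w <= 0) || any(h <= 0))
      stop("invalid shape_spec field 'widths'/'heights': must be positive")
    if (any(diff(w) > 1e-12))
      stop("invalid shape_spec field 'widths': must be non-increasing bottom to top")
    if (max(w) > par$pitch)
      stop("invalid shape_spec field 'pitch': must exceed the bottom step width")
  }
  structure(c(list(kind = kind), par,
              list(max_surface_deviation = max_surface_deviation,
                   max_angle_deviation = max_angle_deviation)),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  par <- x[setdiff(names(x), c("kind", "max_surface_deviation",
                               "max_angle_deviation"))]
  cat(sprintf("shape_spec '%s' (sag <= %g mm, angle <= %g deg)\n",
              x$kind, x$max_surface_deviation, x$max_angle_deviation))
  for (nm in names(par))
    cat(sprintf("  %s: %s\n", nm,
                paste(signif(par[[nm]], 6), collapse = " ")))
  invisible(x)
}

# Smallest number of segments on a circle of radius r so that both the chord
# sag and the step between adjacent facet normals stay within bounds.
.circle_segments <- function(r, sag, angle_deg) {
  a_sag <- 2 * acos(max(-1, 1 - min(sag / r, 2)))
  a_ang <- angle_deg * pi / 180
  a <- min(a_sag, a_ang)
  max(3L, as.integer(ceiling(2 * pi / a)))
}

# --- watertight extrusion of a simple polygon --------------------------------

# Ear-clipping triangulation of a simple CCW polygon (n x 2 matrix, no
# repeated last point).  Returns m x 3 index matrix.
.ear_clip <- function(poly) {
  n <- nrow(poly)
  if (n < 3) stop("polygon needs >= 3 vertices")
  idx <- seq_len(n)
  tris <- matrix(0L, nrow = n - 2L, ncol = 3L)
  k <- 0L
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  in_tri <- function(p, a, b, c) {
    d1 <- cross2(a, b, p); d2 <- cross2(b, c, p); d3 <- cross2(c, a, p)
    (d1 >= 0 & d2 >= 0 & d3 >= 0)
  }
  eps <- 1e-12 * max(abs(poly))^2
  while (length(idx) > 3L) {
    m <- length(idx)
    ear_found <- FALSE
    for (j in seq_len(m)) {
      ip <- idx[(j - 2L) %% m + 1L]
      ic <- idx[(j - 1L) %% m + 1L]
      inx <- idx[j %% m + 1L]
      a <- poly[ip, ]; b <- poly[ic, ]; c <- poly[inx, ]
      if (cross2(a, b, c) <= eps) next     # reflex or degenerate corner
      others <- setdiff(idx, c(ip, ic, inx))
      clear <- TRUE
      for (o in others) {
        if (in_tri(poly[o, ], a, b, c)) { clear <- FALSE; break }
      }
      if (clear) {
        k <- k + 1L
        tris[k, ] <- c(ip, ic, inx)
        idx <- idx[idx != ic]
        ear_found <- TRUE
        break
      }
    }
    if (!ear_found) {
      # drop an exactly collinear vertex if one remains, else give up
      m <- length(idx)
      dropped <- FALSE
      for (j in seq_len(m)) {
        ip <- idx[(j - 2L) %% m + 1L]; ic <- idx[(j - 1L) %% m + 1L]
        inx <- idx[j %% m + 1L]
        if (abs(cross2(poly[ip, ], poly[ic, ], poly[inx, ])) <=
            1e-9 * max(abs(poly))^2) {
          idx <- idx[idx != ic]; dropped <- TRUE; break
        }
      }
      if (!dropped) stop("ear clipping failed: polygon may not be simple")
    }
  }
  k <- k + 1L
  tris[k, ] <- idx
  tris[seq_len(k), , drop = FALSE]
}

# Extrude a simple CCW polygon given in the (x, z) plane along y in
# [y0, y1]; returns a watertight triangle soup (vertex matrix rows).
.extrude_xz <- function(poly, y0, y1) {
  # drop zero-length edges
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  keep <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2)) > 1e-12
  poly <- poly[keep, , drop = FALSE]
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  v3 <- function(p, y) c(p[1], y, p[2])
  verts <- vector("list", 2L * n + 2L)
  # side walls: for CCW polygon in (x, z) seen looking down -y, outward
  # normals point away from the interior when quads are wound (b0, a0, a1).
  sides <- matrix(0, nrow = 6L * n, ncol = 3L)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    a0 <- v3(a, y0); a1 <- v3(a, y1); b0 <- v3(b, y0); b1 <- v3(b, y1)
    sides[(6L * i - 5L):(6L * i), ] <- rbind(b0, a0, a1, b0, a1, b1)
  }
  tri <- .ear_clip(poly)
  caps <- matrix(0, nrow = 6L * nrow(tri), ncol = 3L)
  for (t in seq_len(nrow(tri))) {
    p <- poly[tri[t, 1], ]; q <- poly[tri[t, 2], ]; r <- poly[tri[t, 3], ]
    # cap at y0 faces -y, cap at y1 faces +y
    caps[(6L * t - 5L):(6L * t - 3L), ] <- rbind(v3(p, y0), v3(q, y0), v3(r, y0))
    caps[(6L * t - 2L):(6L * t), ]      <- rbind(v3(r, y1), v3(q, y1), v3(p, y1))
  }
  rbind(sides, caps)
}

# Flip winding if the signed volume is negative (ensures outward orientation
# for a single consistently wound component).
.orient_outward <- function(verts, name) {
  m <- triangle_mesh(verts, name = name)
  r <- .tri_rows(m)
  V <- m$vertices
  A <- V[r$a, , drop = FALSE]; B <- V[r$b, , drop = FALSE]
  C <- V[r$c, , drop = FALSE]
  s <- sum(A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) +
           A[, 2] * (B[, 3] * C[, 1] - B[, 1] * C[, 3]) +
           A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1]))
  if (s < 0) {
    swap <- V[r$b, , drop = FALSE]
    V[r$b, ] <- V[r$c, , drop = FALSE]
    V[r$c, ] <- swap
    m <- triangle_mesh(V, name = name)
  }
  m
}

# --- individual generators ---------------------------------------------------

.make_cube <- function(edge) {
  h <- edge / 2
  poly <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))   # (x, z), CCW
  .orient_outward(.extrude_xz(poly, -h, h), "cube")
}

.make_sphere <- function(radius, sag, angle) {
  # doubly-curved surface: a facet interior deviates by about the sum of the
  # two per-direction chord sags, so each direction gets half the allowance
  n_az <- .circle_segments(radius, sag / 2, angle)
  a_max <- 2 * pi / n_az
  n_pol <- max(2L, as.integer(ceiling(pi / a_max)))
  phi <- seq(0, pi, length.out = n_pol + 1L)       # polar angle, 0 = +z pole
  th <- seq(0, 2 * pi, length.out = n_az + 1L)[-(n_az + 1L)]
  tris <- list()
  ring <- function(p) cbind(radius * sin(p) * cos(th),
                            radius * sin(p) * sin(th),
                            rep(radius * cos(p), n_az))
  rings <- lapply(phi, ring)
  for (i in seq_len(n_pol)) {
    up <- rings[[i]]; lo <- rings[[i + 1L]]
    j2 <- c(2:n_az, 1L)
    if (i == 1L) {                      # top cap fan
      tris[[length(tris) + 1L]] <-
        do.call(rbind, lapply(seq_len(n_az), function(j)
          rbind(c(0, 0, radius), lo[j, ], lo[j2[j], ])))
    } else if (i == n_pol) {            # bottom cap fan
      tris[[length(tris) + 1L]] <-
        do.call(rbind, lapply(seq_len(n_az), function(j)
          rbind(c(0, 0, -radius), up[j2[j], ], up[j, ])))
    } else {
      quads <- lapply(seq_len(n_az), function(j)
        rbind(up[j, ], lo[j, ], lo[j2[j], ],
              up[j, ], lo[j2[j], ], up[j2[j], ]))
      tris[[length(tris) + 1L]] <- do.call(rbind, quads)
    }
  }
  .orient_outward(do.call(rbind, tris), "sphere")
}

.make_cone <- function(radius, height, sag, angle) {
  m <- .circle_segments(radius, sag, angle)
  th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  base <- cbind(radius * cos(th), radius * sin(th), 0)
  apex <- c(0, 0, height)
  ctr <- c(0, 0, 0)
  j2 <- c(2:m, 1L)
  lat <- do.call(rbind, lapply(seq_len(m), function(j)
    rbind(apex, base[j, ], base[j2[j], ])))
  cap <- do.call(rbind, lapply(seq_len(m), function(j)
    rbind(ctr, base[j2[j], ], base[j, ])))
  .orient_outward(rbind(lat, cap), "cone")
}

.make_torus <- function(R, r, sag, angle) {
  # doubly curved: half the sag allowance per direction (see .make_sphere)
  n_maj <- .circle_segments(R + r, sag / 2, angle)
  n_min <- .circle_segments(r, sag / 2, angle)
  u <- seq(0, 2 * pi, length.out = n_maj + 1L)[-(n_maj + 1L)]  # around axis
  v <- seq(0, 2 * pi, length.out = n_min + 1L)[-(n_min + 1L)]  # around tube
  pt <- function(ui, vi) {
    c((R + r * cos(vi)) * cos(ui), (R + r * cos(vi)) * sin(ui), r * sin(vi))
  }
  i2 <- c(2:n_maj, 1L); j2 <- c(2:n_min, 1L)
  tris <- vector("list", n_maj * n_min)
  k <- 0L
  for (i in seq_len(n_maj)) for (j in seq_len(n_min)) {
    a <- pt(u[i], v[j]); b <- pt(u[i2[i]], v[j])
    c_ <- pt(u[i2[i]], v[j2[j]]); d <- pt(u[i], v[j2[j]])
    k <- k + 1L
    tris[[k]] <- rbind(a, b, c_, a, c_, d)
  }
  .orient_outward(do.call(rbind, tris), "torus")
}

.make_rifi1d <- function(base, period, height, n_periods, length) {
  xmax <- n_periods * period
  # cross-section in (x, z), CCW: along the bottom, up the right wall, then
  # the sawtooth ridge line right-to-left, down the left wall
  pts <- list(c(0, 0), c(xmax, 0), c(xmax, base))
  for (i in n_periods:1) {
    x1 <- i * period
    pts[[length(pts) + 1L]] <- c(x1 - period / 2, base + height)
    pts[[length(pts) + 1L]] <- c(x1 - period, base)
  }
  poly <- do.call(rbind, pts)
  if (sqrt(sum((poly[nrow(poly), ] - c(0, base))^2)) > 1e-9)
    poly <- rbind(poly, c(0, base))
  .orient_outward(.extrude_xz(poly, 0, length), "rifi1d")
}

.make_rgf <- function(widths, heights, bar_length, n_bars, pitch) {
  H <- cumsum(heights)
  ns <- length(widths)
  # ziggurat cross-section of one bar centred on x = 0, CCW in (x, z)
  right <- list(c(widths[1] / 2, 0))
  for (i in seq_len(ns)) {
    right[[length(right) + 1L]] <- c(widths[i] / 2, H[i])
    if (i < ns && widths[i + 1L] < widths[i] - 1e-12)
      right[[length(right) + 1L]] <- c(widths[i + 1L] / 2, H[i])
  }
  rgt <- do.call(rbind, right)
  lft <- rgt[nrow(rgt):1, , drop = FALSE]
  lft[, 1] <- -lft[, 1]
  poly <- rbind(rgt, lft)          # bottom edge closes the loop
  bars <- vector("list", n_bars)
  for (b in seq_len(n_bars)) {
    p <- poly
    p[, 1] <- p[, 1] + (b - 1) * pitch
    bars[[b]] <- .orient_outward(.extrude_xz(p, 0, bar_length), "rgf")$vertices
  }
  triangle_mesh(do.call(rbind, bars), name = "rgf")
}

#' Generate a test-geometry mesh
#'
#' Produces a watertight, outward-oriented [triangle_mesh()] for the given
#' [shape_spec()].  Curved surfaces use the smallest segment counts meeting
#' both tessellation bounds; generation is deterministic for a fixed spec.
#'
#' @param spec a [shape_spec()].
#' @return a [triangle_mesh()].
#' @export
make_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  sag <- spec$max_surface_deviation
  ang <- spec$max_angle_deviation
  switch(spec$kind,
    cube   = .make_cube(spec$edge),
    sphere = .make_sphere(spec$radius, sag, ang),
    cone   = .make_cone(spec$radius, spec$height, sag, ang),
    torus  = .make_torus(spec$major_radius, spec$minor_radius, sag, ang),
    rifi1d = .make_rifi1d(spec$base, spec$period, spec$height,
                          spec$n_periods, spec$length),
    rgf    = .make_rgf(spec$widths, spec$heights, spec$bar_length,
                       spec$n_bars, spec$pitch))
}

#' Closed-form volume of the smooth solid
#'
#' Analytic volume of the ideal (untessellated) solid described by a
#' [shape_spec()]: cube `a^3`; sphere `4*pi*r^3/3`; cone `pi*r^2*h/3`; torus
#' `2*pi^2*R*r^2`; ripple filter `L*n*p*base + L*n*p*h/2`; ridge filter
#' `sum(w_i*h_i)*L*n_bars`.
#'
#' @param spec a [shape_spec()].
#' @return volume in cm^3.
#' @export
analytic_volume <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  mm3 <- switch(spec$kind,
    cube   = spec$edge^3,
    sphere = 4 * pi * spec$radius^3 / 3,
    cone   = pi * spec$radius^2 * spec$height / 3,
    torus  = 2 * pi^2 * spec$major_radius * spec$minor_radius^2,
    rifi1d = spec$length * spec$n_periods * spec$period * spec$base +
             0.5 * spec$period * spec$height * spec$n_periods * spec$length,
    rgf    = sum(spec$widths * spec$heights) * spec$bar_length * spec$n_bars)
  mm3 / 1000
}
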