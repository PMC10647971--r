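# Independent oracles and small fixture builders shared across tests.

# Brute-force point-in-polyhedron test by ray casting along +x and counting
# crossing parity against every triangle.  Completely independent of the
# slice-polygonization path used by voxelize().
ray_parity_inside <- function(mesh, pts) {
  V <- mesh$vertices
  nt <- nrow(V) / 3L
  A <- V[seq(1L, by = 3L, length.out = nt), , drop = FALSE]
  B <- V[seq(2L, by = 3L, length.out = nt), , drop = FALSE]
  C <- V[seq(3L, by = 3L, length.out = nt), , drop = FALSE]
  apply(pts, 1, function(p) {
    d1 <- (B[, 2] - A[, 2]) * (p[3] - A[, 3]) - (B[, 3] - A[, 3]) * (p[2] - A[, 2])
    d2 <- (C[, 2] - B[, 2]) * (p[3] - B[, 3]) - (C[, 3] - B[, 3]) * (p[2] - B[, 2])
    d3 <- (A[, 2] - C[, 2]) * (p[3] - C[, 3]) - (A[, 3] - C[, 3]) * (p[2] - C[, 2])
    hit <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    cnt <- 0L
    for (i in which(hit)) {
      M <- rbind(c(B[i, 2] - A[i, 2], C[i, 2] - A[i, 2]),
                 c(B[i, 3] - A[i, 3], C[i, 3] - A[i, 3]))
      if (abs(det(M)) < 1e-12) next
      uv <- solve(M, c(p[2] - A[i, 2], p[3] - A[i, 3]))
      xint <- A[i, 1] + uv[1] * (B[i, 1] - A[i, 1]) + uv[2] * (C[i, 1] - A[i, 1])
      if (xint > p[1]) cnt <- cnt + 1L
    }
    cnt %% 2L == 1L
  })
}

# All voxel-centre coordinates of a voxel_grid, one row per cell, in the
# array's storage order.
voxel_centres <- function(grid) {
  d <- dim(grid$labels)
  ctr <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  sweep(sweep(ctr - 0.5, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

# Exhaustive gamma oracle: for every masked reference point, minimize the
# combined dose-distance term over ALL evaluated points (no search sphere,
# no interpolation).  Grids must share geometry.
gamma_brute_force <- function(reference, evaluated, dose_percent, dta,
                              threshold_percent = 10) {
  dims <- dim(reference$values)
  sp <- reference$spacing
  dmax <- max(reference$values)
  dd <- dose_percent / 100 * dmax
  mask <- reference$values >= threshold_percent / 100 * dmax
  co <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                              k = seq_len(dims[3])))
  pos <- sweep(co - 0.5, 2, sp, "*")
  Dv <- as.vector(reference$values)
  Ev <- as.vector(evaluated$values)
  g <- rep(NA_real_, length(Dv))
  for (idx in which(as.vector(mask))) {
    d2 <- (pos[, 1] - pos[idx, 1])^2 + (pos[, 2] - pos[idx, 2])^2 +
          (pos[, 3] - pos[idx, 3])^2
    g[idx] <- sqrt(min((Ev - Dv[idx])^2 / dd^2 + d2 / dta^2))
  }
  list(gamma = array(g, dims), mask = mask,
       passing_rate = 100 * sum(g[mask] <= 1) / sum(mask))
}

# Coarse test shapes keep the brute-force comparisons fast.
coarse_spec <- function(kind, ...)
  shape_spec(kind, ..., max_surface_deviation = 2, max_angle_deviation = 45)

unit_tetrahedron <- function() {
  triangle_mesh(rbind(
    c(0, 0, 0), c(0, 1, 0), c(1, 0, 0),     # base (outward -z)
    c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
    c(0, 0, 0), c(0, 0, 1), c(0, 1, 0),
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    name = "tetra")
}

# random rotation matrix from a QR decomposition, deterministic under seed
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
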