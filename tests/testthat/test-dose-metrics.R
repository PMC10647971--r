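test_that("crossings interpolate linearly on a triangular curve", {
  tri <- depth_dose_curve(c(0, 10, 20), c(0, 1, 0))
  expect_equal(crossing_depth(tri, 0.8, "distal"), 12)
  expect_equal(crossing_depth(tri, 0.8, "proximal"), 8)
  m <- idd_metrics(tri)
  expect_equal(m$r80, 12)
  expect_equal(m$r20, 18)
  expect_equal(m$dfw, 6)
  expect_equal(m$bpw, 4)
  # scale invariance of every metric
  m5 <- idd_metrics(depth_dose_curve(c(0, 10, 20), 5 * c(0, 1, 0)))
  expect_equal(unclass(m5)[c("r80", "r20", "dfw", "bpw")],
               unclass(m)[c("r80", "r20", "dfw", "bpw")])
  expect_error(crossing_depth(depth_dose_curve(1:4, c(1, 2, 3, 4)), 0.5,
                              "distal"), "no crossing")
})

test_that("metrics on the sampled Bragg fixture match the closed-form oracle", {
  spec <- bragg_spec(r80 = 300, plateau = 0.3, peak_width = 15, falloff = 2)
  curve <- make_bragg_curve(spec, step = 0.5)
  m <- idd_metrics(curve)
  # oracle: root-finding on the generator's closed form
  oracle_crossing <- function(frac, lo, hi)
    stats::uniroot(function(z) bragg_dose(spec, z) - frac * spec$amplitude,
                   c(lo, hi), tol = 1e-12)$root
  zp <- spec$z_peak
  expect_lt(abs(m$r80 - oracle_crossing(0.8, zp, 320)), 0.25)   # half a step
  expect_lt(abs(m$r20 - oracle_crossing(0.2, zp, 320)), 0.25)
  expect_lt(abs(m$proximal80 - oracle_crossing(0.8, 0, zp)), 0.25)
  expect_equal(m$r80, 300, tolerance = 0.25 / 300)
})

test_that("a 0.005 mm depth shift between fixtures is recovered in R80", {
  spec <- bragg_spec(r80 = 300)
  z <- make_bragg_curve(spec, step = 0.5)$depth
  a <- depth_dose_curve(z, bragg_dose(spec, z))
  b <- depth_dose_curve(z, bragg_dose(spec, z - 0.005))
  dr80 <- idd_metrics(b)$r80 - idd_metrics(a)$r80
  expect_equal(dr80, 0.005, tolerance = 0.02)
})

test_that("SOBP width follows the 90%-to-90% definition", {
  trap <- depth_dose_curve(c(0, 95, 100, 110, 115, 120),
                           c(0, 0, 1, 1, 0, 0))
  expect_equal(sobp_width(trap), 11)                 # 10 + 2 * 0.5
  # generated SOBP with 10 mm modulation
  spec <- bragg_spec(r80 = 150, modulation = 10, peak_width = 0.5,
                     falloff = 0.2)
  curve <- make_bragg_curve(spec, step = 0.5)
  expect_lt(abs(sobp_width(curve) - 10), 0.5)        # within one sample step
  # depth shift leaves the width unchanged
  shifted <- depth_dose_curve(curve$depth + 25, curve$dose)
  expect_equal(sobp_width(shifted), sobp_width(curve))
  # near-flat limit: BPW approaches the modulation width
  expect_lt(abs(idd_metrics(curve)$bpw - 10), 0.5)
})

test_that("point-to-point deviation matches a direct per-point loop", {
  spec <- bragg_spec(r80 = 100)
  z <- seq(0.25, 120, by = 0.5)
  a <- bragg_dose(spec, z)
  b <- a * 1.01
  got <- point_to_point_deviation(a, b, threshold_fraction = 0.2)
  # brute-force loop oracle
  mask <- a >= 0.2 * max(a)
  d <- numeric(0)
  for (i in which(mask)) d <- c(d, (b[i] - a[i]) / max(a) * 100)
  expect_equal(unname(got["mean_abs"]), mean(abs(d)))
  expect_equal(unname(got["sd"]), stats::sd(d))
  # identical profiles: 0 +/- 0
  same <- point_to_point_deviation(a, a)
  expect_equal(unname(same), c(0, 0))
  # threshold just below 1 keeps only the maximum point
  top <- point_to_point_deviation(a, b, threshold_fraction = 1 - 1e-9)
  expect_equal(unname(top["mean_abs"]), 1)
  expect_error(point_to_point_deviation(a, b[-1]), "mismatch")
})

test_that("IDD extraction integrates a lateral disc over each slice", {
  spec <- bragg_spec(r80 = 30, peak_width = 5, falloff = 1)
  curve <- make_bragg_curve(spec, step = 1)
  grid <- make_dose_grid(curve, field_size = 10, sigma = 1, spacing = 1)
  # separability: the extracted IDD is proportional to the input curve
  idd <- extract_idd(grid, beam_axis = 3, radius = 4)
  ref <- bragg_dose(spec, idd$depth)
  expect_equal(stats::cor(idd$dose, ref), 1, tolerance = 1e-12)
  # radius beyond the grid equals the full-slice sum
  idd_all <- extract_idd(grid, beam_axis = 3, radius = 1e6)
  full <- apply(grid$values, 3, sum) * prod(grid$spacing[1:2])
  expect_equal(idd_all$dose, full)
  # disc-mask voxel census at the scoring geometry
  sp <- 0.5; radius <- 40.8
  u <- (seq_len(200) - 0.5) * sp
  u <- u - mean(range(u))
  disc <- outer(u, u, function(a, b) sqrt(a^2 + b^2)) <= radius
  expect_equal(sum(disc), sum(sapply(u, function(a)
    sum(sqrt(a^2 + u^2) <= radius))))
  # a sub-voxel radius falls back to the centre row with a warning
  expect_warning(extract_idd(grid, 3, radius = 0.05), "central row")
})

test_that("depth-dose text round trip preserves the samples", {
  curve <- make_bragg_curve(bragg_spec(r80 = 50, falloff = 1), step = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_dose(curve, path)
  back <- read_depth_dose(path)
  expect_equal(back$depth, curve$depth, tolerance = 1e-8)
  expect_equal(back$dose, curve$dose, tolerance = 1e-8)
})

test_that("curve construction enforces the sampling invariants", {
  expect_error(depth_dose_curve(c(0, 1), c(1, 2, 3)), "lengths differ")
  expect_error(depth_dose_curve(c(0, 0, 1), c(1, 2, 3)), "increasing")
  expect_error(depth_dose_curve(c(0, 1, 2), c(0, -1, 0)), "non-negative")
  expect_error(depth_dose_curve(c(0, 1, 2), c(0, 0, 0)), "positive")
})
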