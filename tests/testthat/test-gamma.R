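# small separable dose grid shared across the gamma tests
.gamma_fixture <- function(spacing = 1) {
  spec <- bragg_spec(r80 = 30, peak_width = 5, falloff = 1.5)
  curve <- make_bragg_curve(spec, step = spacing)
  make_dose_grid(curve, field_size = 8, sigma = 1.5, spacing = spacing,
                 lateral_extent = 12)
}

test_that("a grid compared with itself passes everywhere with gamma 0", {
  g <- .gamma_fixture()
  res <- gamma_map(g, g, dose_percent = 1, dta = 1, refine = 1)
  expect_equal(res$passing_rate, 100)
  expect_equal(max(res$gamma[res$mask]), 0)
  expect_true(all(res$gamma[res$mask] >= 0))
  expect_equal(passing_rate(res), 100)
})

test_that("gamma_map equals the exhaustive all-points minimization", {
  # a 0.3 mm shift plus 1% amplitude ripple keeps the dose-only gamma below
  # ~6 everywhere, so a search sphere of 8 DTA provably contains every
  # minimizer and the truncated search must equal the exhaustive one
  spec <- bragg_spec(r80 = 30, peak_width = 5, falloff = 1.5)
  z <- make_bragg_curve(spec, step = 1)$depth
  ref <- make_dose_grid(depth_dose_curve(z, bragg_dose(spec, z)),
                        field_size = 8, sigma = 1.5, spacing = 1,
                        lateral_extent = 9)
  ev <- make_dose_grid(depth_dose_curve(z, bragg_dose(spec, z - 0.3) *
                                          (1 + 0.01 * sin(z))),
                       field_size = 8, sigma = 1.5, spacing = 1,
                       lateral_extent = 9)
  got <- gamma_map(ref, ev, dose_percent = 3, dta = 2, refine = 1,
                   search_factor = 8)
  want <- gamma_brute_force(ref, ev, dose_percent = 3, dta = 2)
  expect_equal(got$gamma[got$mask], want$gamma[want$mask], tolerance = 1e-12)
  expect_equal(got$passing_rate, want$passing_rate)
})

test_that("a sub-spacing spatial shift passes a 1%-1mm criterion", {
  spec <- bragg_spec(r80 = 15, peak_width = 4, falloff = 1)
  z <- make_bragg_curve(spec, step = 0.5)$depth
  ref <- make_dose_grid(depth_dose_curve(z, bragg_dose(spec, z)),
                        field_size = 6, sigma = 1.5, spacing = 0.5,
                        lateral_extent = 3)
  ev <- make_dose_grid(depth_dose_curve(z, bragg_dose(spec, z - 0.5)),
                       field_size = 6, sigma = 1.5, spacing = 0.5,
                       lateral_extent = 3)
  res <- gamma_map(ref, ev, dose_percent = 1, dta = 1, refine = 3)
  expect_equal(res$passing_rate, 100)
})

test_that("uniform 3% scaling under 2%-2mm follows the zero-gradient closed form", {
  # two flat plateaus, far enough apart that searches stay inside each
  vals <- array(0.5, dim = c(9, 9, 24))
  vals[, , 1:12] <- 1
  ref <- dose_grid(vals, spacing = 1)
  ev <- dose_grid(vals * 1.03, spacing = 1)
  res <- gamma_map(ref, ev, dose_percent = 2, dta = 2, refine = 1,
                   threshold_percent = 10)
  # interior plateau points: gamma = 0.03 D / (0.02 Dmax)
  expect_equal(res$gamma[5, 5, 6], 1.5, tolerance = 1e-9)
  expect_equal(res$gamma[5, 5, 19], 0.75, tolerance = 1e-9)
  # passing rate equals the census from the brute-force oracle
  want <- gamma_brute_force(ref, ev, 2, 2)
  expect_equal(res$passing_rate, want$passing_rate)
})

test_that("gamma is scale invariant under global normalization", {
  ref <- .gamma_fixture()
  spec <- bragg_spec(r80 = 30, peak_width = 5, falloff = 1.5)
  z <- make_bragg_curve(spec, step = 1)$depth
  ev <- make_dose_grid(depth_dose_curve(z, bragg_dose(spec, z) *
                                          (1 + 0.02 * sin(z))),
                       field_size = 8, sigma = 1.5, spacing = 1,
                       lateral_extent = 12)
  r1 <- gamma_map(ref, ev, 2, 2, refine = 1)
  ref2 <- dose_grid(ref$values * 7.5, ref$spacing, ref$origin)
  ev2 <- dose_grid(ev$values * 7.5, ev$spacing, ev$origin)
  r2 <- gamma_map(ref2, ev2, 2, 2, refine = 1)
  expect_equal(r1$gamma, r2$gamma, tolerance = 1e-12)
})

test_that("widening criteria never lowers the rate; raising the threshold shrinks the mask", {
  ref <- .gamma_fixture()
  spec <- bragg_spec(r80 = 30, peak_width = 5, falloff = 1.5)
  z <- make_bragg_curve(spec, step = 1)$depth
  ev <- make_dose_grid(depth_dose_curve(z, bragg_dose(spec, z - 0.8) * 1.015),
                       field_size = 8, sigma = 1.5, spacing = 1,
                       lateral_extent = 12)
  r11 <- gamma_map(ref, ev, 1, 1, refine = 1)
  r22 <- gamma_map(ref, ev, 2, 2, refine = 1)
  expect_gte(r22$passing_rate, r11$passing_rate)
  m10 <- gamma_map(ref, ev, 1, 1, refine = 1, threshold_percent = 10)
  m50 <- gamma_map(ref, ev, 1, 1, refine = 1, threshold_percent = 50)
  expect_true(all(m50$mask <= m10$mask))
  expect_lt(sum(m50$mask), sum(m10$mask))
})

test_that("dose grid text round trip and geometry mismatches", {
  g <- .gamma_fixture()
  path <- withr::local_tempfile(fileext = ".txt")
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_equal(back$values, g$values, tolerance = 1e-8)
  expect_equal(back$spacing, g$spacing, tolerance = 1e-9)
  expect_equal(back$origin, g$origin, tolerance = 1e-8)
  other <- dose_grid(g$values, g$spacing * 2, g$origin)
  expect_error(gamma_map(g, other, 1, 1), "spacing or origin")
})
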