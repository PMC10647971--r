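#' Analytic Bragg-curve fixture specification
#'
#' A documented analytic stand-in for a Monte-Carlo-scored integral depth
#' dose, used to exercise the depth-dose metrics without particle
#' transport.  It is not a physical Bragg-curve model (no stopping-power
#' physics).  The closed form, with `zp` the peak depth, is
#' \preformatted{
#'   D(z) = A * (p + (1 - p) * exp(-((z - zs) / sl)^2))   z <= zs
#'   D(z) = A                                             zs <= z <= zp
#'   D(z) = A * exp(-((z - zp) / sr)^2)                   z >= zp
#' }
#' where `zs = zp - modulation` (for a pristine peak `modulation = 0`, so
#' the flat segment is empty), `p` is the entrance-plateau fraction, `sl`
#' the proximal peak-width parameter and `sr` the distal-falloff steepness.
#' The peak depth is placed so that the distal 80% level falls at the
#' requested `r80`: `zp = r80 - sr * sqrt(log(1 / 0.8))`.  All crossing
#' depths therefore have closed forms, e.g. the distal fraction-f crossing
#' is `zp + sr * sqrt(log(1 / f))` and the proximal one is
#' `zs - sl * sqrt(log((1 - p) / (f - p)))` for `f > p`.
#'
#' @param r80 target distal 80% range (mm).
#' @param amplitude peak dose A (arbitrary units).
#' @param plateau entrance plateau level as a fraction of the peak (< 0.8 so
#'   the proximal 80% crossing exists).
#' @param peak_width proximal width parameter `sl` (mm).
#' @param falloff distal falloff steepness parameter `sr` (mm).
#' @param modulation SOBP modulation width (mm); 0 gives a pristine peak.
#' @return an object of class `bragg_spec`.
#' @seealso [bragg_dose()], [make_bragg_curve()]
#' @export
bragg_spec <- function(r80 = 300, amplitude = 1, plateau = 0.3,
                       peak_width = 15, falloff = 2, modulation = 0) {
  if (r80 <= 0 || amplitude <= 0 || peak_width <= 0 || falloff <= 0)
    stop("bragg_spec dimensions must be positive")
  if (plateau <= 0 || plateau >= 0.8)
    stop("'plateau' must be in (0, 0.8) so the 80% crossings exist")
  if (modulation < 0) stop("'modulation' must be >= 0")
  zp <- r80 - falloff * sqrt(log(1 / 0.8))
  if (zp - modulation <= 0)
    stop("r80 too small for the requested falloff/modulation")
  structure(list(r80 = r80, amplitude = amplitude, plateau = plateau,
                 peak_width = peak_width, falloff = falloff,
                 modulation = modulation, z_peak = zp),
            class = "bragg_spec")
}

#' Evaluate the analytic Bragg fixture dose
#'
#' The closed-form depth-dose of a [bragg_spec()], usable as an independent
#' oracle (e.g. root-finding for exact crossing depths).
#'
#' @param spec a [bragg_spec()].
#' @param z depths in mm (vectorized).
#' @return dose values.
#' @export
bragg_dose <- function(spec, z) {
  stopifnot(inherits(spec, "bragg_spec"))
  zp <- spec$z_peak
  zs <- zp - spec$modulation
  p <- spec$plateau
  d <- numeric(length(z))
  lo <- z <= zs
  mid <- z > zs & z < zp
  hi <- z >= zp
  d[lo] <- p + (1 - p) * exp(-((z[lo] - zs) / spec$peak_width)^2)
  d[mid] <- 1
  d[hi] <- exp(-((z[hi] - zp) / spec$falloff)^2)
  spec$amplitude * d
}

#' Sample the analytic Bragg fixture onto a depth grid
#'
#' @param spec a [bragg_spec()].
#' @param step depth sampling step in mm (default 0.5, the scoring
#'   resolution emulated by the fixture).
#' @param z_max maximum depth; defaults to the distal 1% depth plus margin.
#' @return a [depth_dose_curve()].
#' @export
make_bragg_curve <- function(spec, step = 0.5, z_max = NULL) {
  stopifnot(inherits(spec, "bragg_spec"))
  if (step <= 0) stop("'step' must be > 0")
  if (is.null(z_max))
    z_max <- spec$z_peak + spec$falloff * sqrt(log(100)) + 5 * step
  z <- seq(step / 2, z_max, by = step)
  depth_dose_curve(z, bragg_dose(spec, z))
}

#' Build a separable 3D dose grid from a depth-dose curve
#'
#' Emulates a square homogeneous field: `D(x, y, z) = curve(z) F(x) F(y)`
#' with `F` a flat-top lateral profile of half-width `field_size / 2` with
#' error-function edges of width `sigma`, normalized to 1 on the axis.  The
#' grid is centred laterally on the beam axis and deterministic.
#'
#' @param curve a [depth_dose_curve()]; the grid samples its linear
#'   interpolation at slice centres.
#' @param field_size lateral field edge length in mm (e.g. 40 for a
#'   4 x 4 cm field).
#' @param sigma lateral penumbra width parameter in mm.
#' @param spacing grid spacing in mm (scalar or length 3).
#' @param lateral_extent total lateral extent covered (mm); defaults to
#'   `field_size + 8 * sigma`.
#' @return a [dose_grid()] with z along the third axis and depth measured
#'   from the curve's own depth origin.
#' @export
make_dose_grid <- function(curve, field_size = 40, sigma = 2, spacing = 0.5,
                           lateral_extent = NULL) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("'spacing' must be > 0")
  if (is.null(lateral_extent)) lateral_extent <- field_size + 8 * sigma
  # odd counts put one sample exactly on the beam axis, where F = 1
  nx <- max(3L, as.integer(round(lateral_extent / spacing[1])))
  nx <- nx + (1L - nx %% 2L)
  ny <- max(3L, as.integer(round(lateral_extent / spacing[2])))
  ny <- ny + (1L - ny %% 2L)
  zmin <- min(curve$depth); zmax <- max(curve$depth)
  nz <- max(2L, as.integer(floor((zmax - zmin) / spacing[3])) + 1L)
  x <- (seq_len(nx) - 0.5) * spacing[1]; x <- x - mean(range(x))
  y <- (seq_len(ny) - 0.5) * spacing[2]; y <- y - mean(range(y))
  z <- zmin + (seq_len(nz) - 1L) * spacing[3]
  erf <- function(t) 2 * stats::pnorm(t * sqrt(2)) - 1
  a <- field_size / 2
  Fprof <- function(u) {
    raw <- 0.5 * (erf((u + a) / (sigma * sqrt(2))) -
                  erf((u - a) / (sigma * sqrt(2))))
    raw / (0.5 * (erf(a / (sigma * sqrt(2))) * 2))
  }
  cz <- stats::approx(curve$depth, curve$dose, xout = z, rule = 2)$y
  vals <- outer(Fprof(x), Fprof(y)) %o% cz
  dose_grid(vals, spacing = spacing,
            origin = c(x[1] - spacing[1] / 2, y[1] - spacing[2] / 2,
                       z[1] - spacing[3] / 2))
}
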