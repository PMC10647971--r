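#' Construct a depth-dose curve
#'
#' One-dimensional dose versus depth samples, e.g. an integral depth dose
#' (IDD) scored along the beam axis.
#'
#' @param depth strictly increasing sample positions (mm).
#' @param dose non-negative dose values (arbitrary units); at least one must
#'   be positive.
#' @return an object of class `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depth, dose) {
  depth <- as.numeric(depth); dose <- as.numeric(dose)
  if (length(depth) != length(dose)) stop("depth and dose lengths differ")
  if (length(depth) < 2) stop("a curve needs at least 2 samples")
  if (any(diff(depth) <= 0)) stop("depth must be strictly increasing")
  if (any(!is.finite(depth)) || any(!is.finite(dose)))
    stop("depth and dose must be finite")
  if (any(dose < 0)) stop("dose must be non-negative")
  if (max(dose) <= 0) stop("maximum dose must be positive")
  structure(list(depth = depth, dose = dose), class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("depth_dose_curve: %d samples, depth %g..%g mm, max dose %.4g at %g mm\n",
              length(x$depth), min(x$depth), max(x$depth), max(x$dose),
              x$depth[which.max(x$dose)]))
  invisible(x)
}

#' Depth where a curve crosses a fractional dose level
#'
#' The level is `fraction * max(dose)` (global, unsmoothed maximum).  The
#' distal crossing is the deepest downward crossing of the level, found by
#' linear interpolation between the bracketing samples; the proximal
#' crossing is the shallowest upward crossing at or before the global
#' maximum.
#'
#' @param curve a [depth_dose_curve()].
#' @param fraction dose fraction in (0, 1).
#' @param side `"distal"` or `"proximal"`.
#' @return depth in mm.
#' @export
crossing_depth <- function(curve, fraction, side = c("distal", "proximal")) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  side <- match.arg(side)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)")
  z <- curve$depth; d <- curve$dose
  level <- fraction * max(d)
  n <- length(d)
  if (side == "distal") {
    down <- which(d[-n] >= level & d[-1] < level)
    if (!length(down)) stop("no crossing: dose never falls through ",
                            fraction * 100, "% distally")
    i <- max(down)
  } else {
    imax <- which.max(d)
    up <- which(d[-n] < level & d[-1] >= level)
    up <- up[up < imax]
    if (!length(up)) stop("no crossing: dose never rises through ",
                          fraction * 100, "% proximally")
    i <- min(up)
  }
  z[i] + (level - d[i]) / (d[i + 1] - d[i]) * (z[i + 1] - z[i])
}

#' Depth-dose summary metrics
#'
#' Computes the standard Bragg-curve descriptors: the beam range R80 (distal
#' 80% dose level), R20 (distal 20%), the distal falloff width
#' DFW = R20 - R80, the Bragg peak width BPW (proximal-to-distal 80%
#' distance), and, when the curve admits 90% crossings on both sides, the
#' SOBP width (proximal-to-distal 90% distance, `NA` otherwise).
#'
#' @param curve a [depth_dose_curve()] that rises monotonically through the
#'   80% level before its maximum and falls through it after.
#' @return an object of class `idd_metrics`: list with elements `r80`,
#'   `r20`, `dfw`, `bpw`, `proximal80`, `sobp_width` (mm).
#' @export
idd_metrics <- function(curve) {
  r80 <- crossing_depth(curve, 0.8, "distal")
  r20 <- crossing_depth(curve, 0.2, "distal")
  p80 <- crossing_depth(curve, 0.8, "proximal")
  sobp <- tryCatch(sobp_width(curve), error = function(e) NA_real_)
  structure(list(r80 = r80, r20 = r20, dfw = r20 - r80,
                 bpw = r80 - p80, proximal80 = p80, sobp_width = sobp),
            class = "idd_metrics")
}

#' @export
print.idd_metrics <- function(x, ...) {
  cat(sprintf("R80  %8.3f mm   (distal 80%% range)\n", x$r80))
  cat(sprintf("R20  %8.3f mm   (distal 20%%)\n", x$r20))
  cat(sprintf("DFW  %8.3f mm   (80%% -> 20%% distal falloff)\n", x$dfw))
  cat(sprintf("BPW  %8.3f mm   (proximal 80%% -> distal 80%%)\n", x$bpw))
  if (!is.na(x$sobp_width))
    cat(sprintf("SOBP %8.3f mm   (proximal 90%% -> distal 90%%)\n",
                x$sobp_width))
  invisible(x)
}

#' Spread-out Bragg peak width
#'
#' Distance between the proximal and distal 90% dose levels.
#'
#' @param curve a [depth_dose_curve()].
#' @return width in mm.
#' @export
sobp_width <- function(curve) {
  crossing_depth(curve, 0.9, "distal") - crossing_depth(curve, 0.9, "proximal")
}

#' Point-to-point deviation between two dose profiles
#'
#' Restricted to samples where the reference profile is at or above
#' `threshold_fraction` of its maximum, computes per-point deviations
#' `d_i = (b_i - a_i) / max(a) * 100` (percent of the reference maximum) and
#' returns the mean of `|d_i|` together with the standard deviation of the
#' signed `d_i` (the "mean +/- SD" convention in which the quoted mean is of
#' absolute deviations while the spread is of signed ones).
#'
#' @param a reference profile: a [depth_dose_curve()] or numeric vector.
#' @param b test profile on the identical sampling.
#' @param threshold_fraction mask threshold in `[0, 1)` relative to `max(a)`.
#' @return named numeric: `mean_abs` and `sd` (both percent).
#' @export
point_to_point_deviation <- function(a, b, threshold_fraction = 0) {
  if (inherits(a, "depth_dose_curve") || inherits(b, "depth_dose_curve")) {
    if (!(inherits(a, "depth_dose_curve") && inherits(b, "depth_dose_curve")))
      stop("profile sampling mismatch: mixed curve and vector inputs")
    if (length(a$depth) != length(b$depth) ||
        any(abs(a$depth - b$depth) > 1e-9))
      stop("profile sampling mismatch: depth grids differ")
    av <- a$dose; bv <- b$dose
  } else {
    av <- as.numeric(a); bv <- as.numeric(b)
    if (length(av) != length(bv))
      stop("profile sampling mismatch: lengths differ")
  }
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must be in [0, 1)")
  ref_max <- max(av)
  mask <- av >= threshold_fraction * ref_max
  d <- (bv[mask] - av[mask]) / ref_max * 100
  c(mean_abs = mean(abs(d)), sd = stats::sd(d))
}

#' Extract an integral depth dose from a 3D dose grid
#'
#' For each slice along the beam axis, sums the dose over voxels whose
#' lateral centre distance from the beam axis (the lateral midline of the
#' grid) is at most `radius`, multiplied by the voxel cross-sectional area.
#' This emulates scoring with a circular detection region.
#'
#' @param grid a [dose_grid()].
#' @param beam_axis axis index along which depth runs (default 3 = z).
#' @param radius detection-region radius in mm (default 40.8, i.e. 4.08 cm).
#' @return a [depth_dose_curve()] with depths at slice centres.
#' @export
extract_idd <- function(grid, beam_axis = 3L, radius = 40.8) {
  stopifnot(inherits(grid, "dose_grid"))
  beam_axis <- as.integer(beam_axis)
  if (!beam_axis %in% 1:3) stop("'beam_axis' must be 1, 2 or 3")
  if (radius <= 0) stop("'radius' must be > 0")
  dims <- dim(grid$values)
  lat <- setdiff(1:3, beam_axis)
  sp <- grid$spacing
  # lateral centre coordinates relative to the lateral midline
  u <- (seq_len(dims[lat[1]]) - 0.5) * sp[lat[1]]
  v <- (seq_len(dims[lat[2]]) - 0.5) * sp[lat[2]]
  u <- u - mean(range(u)); v <- v - mean(range(v))
  if (radius < min(sp[lat]) / 2) {
    warning("detection radius smaller than one voxel; using the central row")
    disc <- outer(abs(u) == min(abs(u)), abs(v) == min(abs(v)), "&")
  } else {
    disc <- outer(u, v, function(a, b) sqrt(a^2 + b^2)) <= radius
  }
  area <- sp[lat[1]] * sp[lat[2]]
  vals <- aperm(grid$values, c(lat, beam_axis))
  nz <- dims[beam_axis]
  idd <- vapply(seq_len(nz), function(k) sum(vals[, , k][disc]) * area,
                numeric(1))
  depth <- grid$origin[beam_axis] + (seq_len(nz) - 0.5) * sp[beam_axis]
  depth_dose_curve(depth, idd)
}

#' Read a depth-dose curve from 2-column delimited text
#' @param path file with two whitespace-delimited columns: depth (mm) and
#'   dose.  Lines starting with `#` are skipped.
#' @return a [depth_dose_curve()].
#' @export
read_depth_dose <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           sep = "", header = FALSE,
                           col.names = c("depth", "dose"))
  depth_dose_curve(tab$depth, tab$dose)
}

#' Write a depth-dose curve as 2-column text
#' @param curve a [depth_dose_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_dose <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  writeLines(c("# depth_mm dose",
               sprintf("%.9g %.9g", curve$depth, curve$dose)), path)
  invisible(path)
}
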