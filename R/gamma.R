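#' Construct a 3D dose grid
#'
#' Scalar dose on a regular 3D lattice.  Grid point `(i, j, k)` (1-based)
#' sits at `origin + (index - 1/2) * spacing` per axis.
#'
#' @param values dense 3D array of non-negative dose values with a positive
#'   maximum.
#' @param spacing numeric length-3 (or scalar) grid spacing in mm.
#' @param origin numeric length-3 lattice minimum corner in mm.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (any(values < 0)) stop("dose values must be non-negative")
  if (max(values) <= 0) stop("maximum dose must be positive")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)")
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dose_grid: %d x %d x %d points, spacing %.4g x %.4g x %.4g mm, max %.4g\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              max(x$values)))
  invisible(x)
}

# trilinear refinement of a 3D array by an integer factor per axis:
# fine points span the original centre-to-centre extent at spacing d/k.
.refine_trilinear <- function(a, k) {
  if (k == 1L) return(a)
  up1 <- function(m, along, k) {
    # linear interpolation along one dimension of a 3D array
    n <- dim(m)[along]
    if (n == 1L) return(m)
    pos <- seq(1, n, by = 1 / k)
    i0 <- pmin(floor(pos), n - 1L)
    w <- pos - i0
    idx0 <- function(i) switch(along,
      m[i, , , drop = FALSE], m[, i, , drop = FALSE], m[, , i, drop = FALSE])
    lo <- idx0(i0); hi <- idx0(i0 + 1L)
    # weight array varying along dimension 'along'
    ww <- switch(along,
      array(w, dim = dim(lo)),
      aperm(array(w, dim = dim(lo)[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(w, dim = dim(lo)[c(3, 1, 2)]), c(2, 3, 1)))
    lo * (1 - ww) + hi * ww
  }
  a <- up1(a, 1L, k); a <- up1(a, 2L, k); up1(a, 3L, k)
}

#' 3D gamma-index map between two dose grids
#'
#' Computes the gamma index of `evaluated` against `reference` under a
#' `dose_percent` / `dta` criterion with global normalization: for each
#' reference point r above the low-dose threshold,
#' `gamma(r) = min_e sqrt((D_e - D_r)^2 / (dose_percent * Dmax / 100)^2 +
#' |x_e - x_r|^2 / dta^2)`, the minimum running over evaluated-grid points
#' within a search sphere of radius `search_factor * dta`, with `Dmax` the
#' global maximum of the reference grid.  The evaluated grid is subdivided
#' by trilinear interpolation at integer factor `refine` inside the search
#' sphere to mitigate discretization bias.  Points whose true minimum lies
#' outside the search sphere are reported at the capped (searched) minimum.
#'
#' Both grids must share shape, spacing and origin.
#'
#' @param reference reference [dose_grid()] (defines normalization and the
#'   threshold mask).
#' @param evaluated evaluated [dose_grid()].
#' @param dose_percent dose-difference criterion in percent of the global
#'   maximum (e.g. 1 for "1%").
#' @param dta distance-to-agreement criterion in mm.
#' @param threshold_percent low-dose threshold: reference points below this
#'   percent of the reference maximum are excluded (default 10).
#' @param search_factor search-sphere radius in units of `dta` (default 3).
#' @param refine integer trilinear subdivision factor for the evaluated grid
#'   (default 3; 1 disables interpolation).
#' @return an object of class `gamma_result`: list with `gamma` (3D array,
#'   `NA` outside the mask), `mask` (logical 3D array), `passing_rate`
#'   (percent of masked points with gamma <= 1) and `criteria`.
#' @export
gamma_map <- function(reference, evaluated, dose_percent, dta,
                      threshold_percent = 10, search_factor = 3,
                      refine = 3L) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (dose_percent <= 0 || dta <= 0)
    stop("'dose_percent' and 'dta' must be > 0")
  if (!identical(dim(reference$values), dim(evaluated$values)))
    stop("grids do not overlap: shapes differ")
  if (any(abs(reference$spacing - evaluated$spacing) > 1e-9) ||
      any(abs(reference$origin - evaluated$origin) > 1e-9))
    stop("grids do not overlap: spacing or origin differ")
  refine <- max(1L, as.integer(refine))
  dims <- dim(reference$values)
  sp <- reference$spacing
  dmax <- max(reference$values)
  dd <- dose_percent / 100 * dmax
  mask <- reference$values >= threshold_percent / 100 * dmax
  if (!any(mask)) stop("empty evaluable mask: threshold excludes every point")

  E <- .refine_trilinear(evaluated$values, refine)
  fsp <- sp / refine
  rad <- search_factor * dta
  # candidate fine-lattice offsets within the search sphere, sorted by distance
  off <- lapply(1:3, function(ax) {
    m <- floor(rad / fsp[ax])
    (-m):m
  })
  og <- expand.grid(a = off[[1]], b = off[[2]], c = off[[3]])
  dist2 <- (og$a * fsp[1])^2 + (og$b * fsp[2])^2 + (og$c * fsp[3])^2
  keep <- dist2 <= rad^2
  og <- og[keep, ]; dist2 <- dist2[keep]
  ord <- order(dist2)
  og <- og[ord, ]; dist2 <- dist2[ord]

  # reference point (i,j,k) corresponds to fine index (i-1)*refine + 1
  fi <- (seq_len(dims[1]) - 1L) * refine + 1L
  fj <- (seq_len(dims[2]) - 1L) * refine + 1L
  fk <- (seq_len(dims[3]) - 1L) * refine + 1L
  fdim <- dim(E)
  D <- reference$values
  g2 <- array(Inf, dim = dims)
  for (t in seq_len(nrow(og))) {
    dterm <- dist2[t] / dta^2
    cur_max <- max(g2[mask])
    if (dterm >= cur_max) break        # remaining offsets cannot improve
    a <- og$a[t]; b <- og$b[t]; c_ <- og$c[t]
    ii <- which(fi + a >= 1L & fi + a <= fdim[1])
    jj <- which(fj + b >= 1L & fj + b <= fdim[2])
    kk <- which(fk + c_ >= 1L & fk + c_ <= fdim[3])
    if (!length(ii) || !length(jj) || !length(kk)) next
    Ev <- E[fi[ii] + a, fj[jj] + b, fk[kk] + c_, drop = FALSE]
    cand <- (Ev - D[ii, jj, kk, drop = FALSE])^2 / dd^2 + dterm
    g2[ii, jj, kk] <- pmin(g2[ii, jj, kk, drop = FALSE], cand)
  }
  gamma <- sqrt(g2)
  gamma[!mask] <- NA_real_
  pr <- 100 * sum(gamma[mask] <= 1) / sum(mask)
  structure(list(gamma = gamma, mask = mask, passing_rate = pr,
                 criteria = list(dose_percent = dose_percent, dta = dta,
                                 threshold_percent = threshold_percent,
                                 normalization = "global",
                                 search_factor = search_factor,
                                 refine = refine)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat(sprintf("gamma_result: %g%%-%g mm (threshold %g%%, global normalization)\n",
              cr$dose_percent, cr$dta, cr$threshold_percent))
  cat(sprintf("  evaluable points: %d; passing rate: %.1f%%\n",
              sum(x$mask), x$passing_rate))
  invisible(x)
}

#' Gamma passing rate
#'
#' Percentage of evaluable (above-threshold) points with gamma <= 1.
#'
#' @param result a [gamma_result][gamma_map()].
#' @return percentage in `[0, 100]`.
#' @export
passing_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  if (!any(result$mask)) stop("empty evaluable mask")
  100 * sum(result$gamma[result$mask] <= 1) / sum(result$mask)
}

#' Write a dose grid as delimited text
#'
#' Layout: a 6-number header line `nx ny nz sx sy sz` (counts and spacing in
#' mm), an optional `origin x y z` line (mm), then values whitespace-
#' separated with the x index fastest.
#'
#' @param grid a [dose_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(d, sprintf("%.9g", grid$spacing)), collapse = " "), con)
  writeLines(paste("origin", paste(sprintf("%.9g", grid$origin),
                                   collapse = " ")), con)
  for (k in seq_len(d[3]))
    writeLines(paste(sprintf("%.9g", grid$values[, , k]), collapse = " "),
               con)
  invisible(path)
}

#' Read a dose grid written by [write_dose_grid()]
#' @param path file path.
#' @return a [dose_grid()].
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) stop("dose grid file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- scan(con, what = double(), n = 6, quiet = TRUE)
  if (length(hdr) != 6) stop("malformed dose grid header: expected 6 numbers")
  counts <- as.integer(hdr[1:3]); spacing <- hdr[4:6]
  origin <- c(0, 0, 0)
  first <- scan(con, what = character(), n = 1, quiet = TRUE)
  if (length(first) && first == "origin") {
    origin <- scan(con, what = double(), n = 3, quiet = TRUE)
    body <- scan(con, what = double(), quiet = TRUE)
  } else {
    body <- c(as.numeric(first), scan(con, what = double(), quiet = TRUE))
  }
  if (length(body) != prod(counts))
    stop(sprintf("dose grid body length mismatch: expected %d, found %d",
                 prod(counts), length(body)))
  dose_grid(array(body, dim = counts), spacing = spacing, origin = origin)
}
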