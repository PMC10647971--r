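#' Write a voxel grid to the FLUKA exchange text format
#'
#' Serializes a [voxel_grid()] to the plain-text layout consumed by a
#' matching `writegolem.f` user routine when building a FLUKA voxel
#' structure.  The layout is this package's documented contract:
#' \preformatted{
#'   nx ny nz            voxel counts
#'   dx dy dz            voxel sizes in cm (>= 7 significant digits)
#'   n_materials         largest entity label (0 = ambient is implicit)
#'   origin x y z        lattice minimum corner in cm (optional line)
#'   <labels>            whitespace-separated, x index fastest, then y, then z
#' }
#' The x-fastest body order matches the Fortran default array fill.  Writing
#' streams one z-slice at a time, so memory stays constant beyond a slice.
#'
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @param write_origin include the `origin` line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_voxel_txt <- function(grid, path, write_origin = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", d[1], d[2], d[3]), con)
  writeLines(paste(sprintf("%.9g", grid$voxel_size / 10), collapse = " "), con)
  writeLines(sprintf("%d", max(1L, max(grid$labels))), con)
  if (write_origin)
    writeLines(paste("origin",
                     paste(sprintf("%.9g", grid$origin / 10), collapse = " ")),
               con)
  for (k in seq_len(d[3])) {
    slice <- grid$labels[, , k]                 # x fastest within each y row
    rows <- apply(matrix(slice, d[1], d[2]), 2,
                  function(col) paste(col, collapse = " "))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a voxel grid from the FLUKA exchange text format
#'
#' Inverse of [write_voxel_txt()]; labels are recovered exactly.  When no
#' `origin` line is present the origin is `(0, 0, 0)`.
#'
#' @param path file path.
#' @return a [voxel_grid()] (sizes converted back to mm).
#' @export
read_voxel_txt <- function(path) {
  if (!file.exists(path)) stop("voxel text file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  counts <- scan(con, what = integer(), n = 3, quiet = TRUE)
  if (length(counts) != 3 || any(counts < 1))
    stop("malformed voxel text header: expected 3 positive voxel counts")
  sizes <- scan(con, what = double(), n = 3, quiet = TRUE)
  if (length(sizes) != 3 || any(sizes <= 0))
    stop("malformed voxel text header: expected 3 positive voxel sizes (cm)")
  nmat <- scan(con, what = integer(), n = 1, quiet = TRUE)
  if (length(nmat) != 1 || nmat < 1)
    stop("malformed voxel text header: expected a positive material count")
  origin <- c(0, 0, 0)
  first <- scan(con, what = character(), n = 1, quiet = TRUE)
  if (length(first) && first == "origin") {
    origin <- scan(con, what = double(), n = 3, quiet = TRUE) * 10
    body <- scan(con, what = integer(), quiet = TRUE)
  } else {
    body <- c(as.integer(first), scan(con, what = integer(), quiet = TRUE))
  }
  expected <- prod(as.numeric(counts))
  if (length(body) != expected)
    stop(sprintf("voxel body length mismatch: expected %d labels, found %d",
                 expected, length(body)))
  if (any(body > nmat))
    stop(sprintf("voxel label %d exceeds declared material count %d",
                 max(body), nmat))
  if (any(body < 0)) stop("negative voxel label in body")
  voxel_grid(array(body, dim = counts), voxel_size = sizes * 10,
             origin = origin)
}

# one fixed-width 10-character FLUKA card field
.card_field <- function(x) {
  if (is.numeric(x)) sprintf("%10.4g", x) else sprintf("%-10s", substr(x, 1, 10))
}

#' Write a FLUKA VOXELS card snippet
#'
#' Emits a text fragment for inclusion in a FLUKA input deck: comment lines
#' documenting the intended material assignment (entity label 1 -> PMMA,
#' empty label 0 -> AIR) and a fixed-format `VOXELS` card carrying the
#' structure corner (cm) in WHAT(1..3) and the voxel-file stem in the SDUM
#' field.  Fields are 10 characters wide, 8 fields per card.
#'
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @param corner corner of the voxel structure in cm; defaults to the grid
#'   origin converted mm to cm.
#' @param stem voxel-file stem for the SDUM field (default `"golem"`).
#' @return `path`, invisibly.
#' @export
write_fluka_snippet <- function(grid, path, corner = NULL, stem = "golem") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(corner)) corner <- grid$origin / 10
  stopifnot(length(corner) == 3, all(is.finite(corner)))
  card <- paste0(.card_field("VOXELS"),
                 .card_field(corner[1]), .card_field(corner[2]),
                 .card_field(corner[3]),
                 .card_field(""), .card_field(""), .card_field(""),
                 sprintf("%-10s", substr(stem, 1, 10)))
  lines <- c("* voxel structure generated by flukavox",
             "* material assignment intent: label 1 (entity) -> PMMA",
             "*                             label 0 (empty)  -> AIR",
             card)
  writeLines(lines, path)
  invisible(path)
}
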