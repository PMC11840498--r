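#' Binary structure volume
#'
#' A `binary_volume` is the in-memory representation of one structure
#' contour: a 3D logical occupancy grid (index order x, y, z) together with
#' the voxel spacing in mm along each axis and the physical position of the
#' centre of voxel `[1, 1, 1]` in mm. All geometric computations in the
#' package (surface extraction, surface Dice, morphological edits) are done
#' in physical coordinates, so anisotropic grids — e.g. 1 x 1 x 2.5 mm CT
#' resolution — are handled correctly.
#'
#' @param grid A 3D array; coerced to logical (non-zero is foreground).
#' @param spacing_mm Numeric length 3, voxel spacing in mm; all > 0.
#' @param origin_mm Numeric length 3, physical coordinates (mm) of the centre
#'   of the first voxel. Defaults to `c(0, 0, 0)`.
#' @return An object of class `binary_volume`: a list with elements `grid`,
#'   `spacing_mm`, `origin_mm`.
#' @examples
#' g <- array(FALSE, c(8, 8, 8)); g[3:6, 3:6, 3:6] <- TRUE
#' v <- binary_volume(g, spacing_mm = c(1, 1, 2.5))
#' v
#' @export
binary_volume <- function(grid, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (any(dim(grid) < 1L))
    stop("all grid dimensions must be >= 1", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers", call. = FALSE)
  storage.mode(grid) <- "logical"
  if (anyNA(grid))
    stop("`grid` contains missing values; occupancy must be strictly binary",
         call. = FALSE)
  structure(list(grid = grid, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<binary_volume> %d x %d x %d voxels, spacing %s mm, %d foreground\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = " x "),
              sum(x$grid)))
  invisible(x)
}

#' @export
dim.binary_volume <- function(x) dim(x$grid)

#' Number of foreground voxels
#' @param volume A [binary_volume()].
#' @return Integer count of foreground voxels.
#' @export
n_foreground <- function(volume) {
  stopifnot(inherits(volume, "binary_volume"))
  sum(volume$grid)
}

# shared-grid contract for every pairwise metric
check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "binary_volume"), inherits(b, "binary_volume"))
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("grid mismatch: volumes have different dimensions", call. = FALSE)
  if (!isTRUE(all.equal(a$spacing_mm, b$spacing_mm, tolerance = 0)) ||
      !isTRUE(all.equal(a$origin_mm, b$origin_mm, tolerance = 0)))
    stop("grid mismatch: volumes have different spacing or origin", call. = FALSE)
  invisible(TRUE)
}

#' Read a structure mask from a NIfTI file
#'
#' Reads a 3D NIfTI-1 volume (`.nii` or `.nii.gz`) and thresholds it at
#' `value > 0`, so label maps stored as 0/1, 0/255 or floating point all load
#' to the same occupancy grid. Spacing and origin are taken from the file
#' header (the sform/qform translation gives the origin).
#'
#' @param path Path to a NIfTI file.
#' @return A [binary_volume()].
#' @export
read_mask <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img_arr <- array(as.vector(img)[seq_len(prod(d[1:3]))], dim = d[1:3])
  } else if (length(d) == 3L) {
    img_arr <- as.array(img)
  } else {
    stop("'", path, "' is not a 3D volume (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  }
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  binary_volume(img_arr > 0, spacing_mm = spacing, origin_mm = origin)
}

#' Write a structure mask to a NIfTI file
#'
#' Foreground is written as 1, background as 0 (uint8). Spacing goes into
#' `pixdim` and the origin into an axis-aligned sform/qform, so
#' `read_mask(write_mask(v, f))` preserves the foreground voxel set, spacing
#' and origin exactly (values chosen representable in single precision, as
#' NIfTI-1 headers store them).
#'
#' @param volume A [binary_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(volume, path) {
  stopifnot(inherits(volume, "binary_volume"))
  arr <- array(as.integer(volume$grid), dim = dim(volume$grid))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing_mm
  m <- diag(c(volume$spacing_mm, 1))
  m[1:3, 4] <- volume$origin_mm
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
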