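#' Extract the voxel surface of a structure
#'
#' The surface of a binary structure is the set of foreground voxels with at
#' least one face-adjacent (6-connectivity) background neighbour; voxels
#' outside the grid count as background, so structures touching the grid edge
#' contribute their edge voxels. Surface elements are voxel centres counted
#' with unit weight; positions are reported in physical mm,
#' `origin + (index - 1) * spacing`.
#'
#' @param mask A [binary_volume()].
#' @return A list of class `surface_set` with `positions_mm` (n x 3 matrix),
#'   `indices` (linear indices into the grid) and `count`.
#' @examples
#' g <- array(FALSE, c(5, 5, 5)); g[2:4, 2:4, 2:4] <- TRUE
#' extract_surface(binary_volume(g))$count  # 26: all cube voxels but the centre
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  d <- dim(mask$grid)
  border <- .border_voxels(as.logical(mask$grid), as.integer(d))
  idx <- which(border)
  ijk <- arrayInd(idx, d)
  pos <- sweep(sweep(ijk - 1, 2, mask$spacing_mm, "*"), 2, mask$origin_mm, "+")
  structure(list(positions_mm = pos, indices = idx, count = length(idx)),
            class = "surface_set")
}

#' Surface Dice similarity coefficient at a distance tolerance
#'
#' The surface Dice similarity coefficient (sDSC) at tolerance `tol_mm` is
#' the fraction of the two structures' combined surface that lies within
#' `tol_mm` of the other structure's surface:
#' \deqn{sDSC = \frac{|\{s \in S_a : d(s, S_b) \le \tau\}| +
#'                    |\{s \in S_b : d(s, S_a) \le \tau\}|}{|S_a| + |S_b|}}
#' where \eqn{S_a, S_b} are the voxel surfaces and \eqn{d} is Euclidean
#' distance in mm honouring anisotropic voxel spacing. A value of 1 means the
#' whole surface agrees to within the tolerance; small boundary shifts below
#' `tol_mm` are deemed clinically negligible. Distances are computed with an
#' exact Euclidean distance transform seeded on the opposite surface's voxel
#' centres, and the comparison is done on squared distances so borderline
#' points at exactly `tol_mm` are classified consistently.
#'
#' Both surfaces empty returns 1 (an absent structure left absent is no
#' edit); exactly one empty returns 0 (a structure fully added or deleted is
#' maximal editing).
#'
#' @param a,b [binary_volume()] objects on an identical grid.
#' @param tol_mm Positive distance tolerance in mm (the clinical audit this
#'   package supports used 3 mm).
#' @return A number in \[0, 1\].
#' @seealso [volumetric_dice()], [is_geometrically_identical()]
#' @examples
#' g <- array(FALSE, c(12, 12, 12)); g[3:8, 3:8, 3:8] <- TRUE
#' h <- array(FALSE, c(12, 12, 12)); h[5:10, 3:8, 3:8] <- TRUE  # shifted 2 voxels
#' a <- binary_volume(g); b <- binary_volume(h)
#' surface_dice(a, b, tol_mm = 3)   # 1: every surface point within 2 mm
#' surface_dice(a, b, tol_mm = 0.5) # < 1
#' @export
surface_dice <- function(a, b, tol_mm) {
  check_same_grid(a, b)
  if (!is.numeric(tol_mm) || length(tol_mm) != 1L || !is.finite(tol_mm) || tol_mm <= 0)
    stop("`tol_mm` must be a single positive number", call. = FALSE)
  d <- as.integer(dim(a$grid))
  sa <- .border_voxels(as.logical(a$grid), d)
  sb <- .border_voxels(as.logical(b$grid), d)
  na <- sum(sa)
  nb <- sum(sb)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  t2 <- tol_mm * tol_mm
  d2_to_b <- .sq_distance_transform(sb, d, a$spacing_mm)
  d2_to_a <- .sq_distance_transform(sa, d, a$spacing_mm)
  (sum(d2_to_b[sa] <= t2) + sum(d2_to_a[sb] <= t2)) / (na + nb)
}

#' Test whether two structures are geometrically identical
#'
#' Voxel-exact equality of the foreground sets, the criterion for a contour
#' having been used clinically with no edit at all.
#'
#' @inheritParams surface_dice
#' @return `TRUE` iff the foreground voxel sets are exactly equal.
#' @export
is_geometrically_identical <- function(a, b) {
  check_same_grid(a, b)
  identical(as.vector(a$grid), as.vector(b$grid))
}

#' Volumetric Dice similarity coefficient
#'
#' Classical Dice overlap of the foreground voxel sets,
#' \eqn{2|A \cap B| / (|A| + |B|)}. Provided for comparison with the surface
#' Dice, which tracks editing effort more closely than volume overlap does.
#' Both volumes empty returns 1.
#'
#' @inheritParams surface_dice
#' @return A number in \[0, 1\].
#' @export
volumetric_dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$grid)
  nb <- sum(b$grid)
  if (na + nb == 0L) return(1)
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Euclidean distance map to a voxel set (mm)
#'
#' Distance from every voxel centre to the nearest `TRUE` voxel centre of
#' `seeds`, in physical mm with anisotropic spacing. Used internally by
#' [surface_dice()] and by the morphological margin edits of the synthetic
#' generator; exported because distance maps are broadly useful for contour
#' QA.
#'
#' @param seeds Logical 3D array (or [binary_volume()]) of seed voxels.
#' @param spacing_mm Voxel spacing, ignored when `seeds` is a
#'   `binary_volume`.
#' @param squared Return squared distances (exact; no square root taken).
#' @return Numeric array of distances, same dimensions as `seeds`; `Inf`
#'   everywhere if there are no seeds.
#' @export
distance_map <- function(seeds, spacing_mm = c(1, 1, 1), squared = FALSE) {
  if (inherits(seeds, "binary_volume")) {
    spacing_mm <- seeds$spacing_mm
    seeds <- seeds$grid
  }
  stopifnot(length(dim(seeds)) == 3L)
  d2 <- .sq_distance_transform(as.logical(seeds), as.integer(dim(seeds)),
                               as.numeric(spacing_mm))
  out <- if (squared) d2 else sqrt(d2)
  array(out, dim = dim(seeds))
}
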