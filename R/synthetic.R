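#' Analytic shape specification
#'
#' Base shapes for synthetic organ-at-risk structures: an ellipsoid stands in
#' for compact, parallel organs (bladder-like), a tube along z for serial,
#' elongated organs (spinal-cord- or oesophagus-like) whose characteristic
#' edit is a change of longitudinal extent.
#'
#' @param kind `"ellipsoid"` or `"tube"`.
#' @param center_mm Shape centre in physical mm.
#' @param radii_mm Ellipsoid semi-axes in mm (length 3).
#' @param radius_mm,length_mm Tube cross-section radius and z length in mm.
#' @param grid_shape Grid dimensions (voxels).
#' @param spacing_mm Voxel spacing in mm.
#' @param margin_mm Required clearance between the shape and the grid
#'   boundary, so dilation edits and the distance tolerance stay inside the
#'   grid. Checked at construction.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("ellipsoid", "tube"), center_mm, radii_mm = NULL,
                       radius_mm = NULL, length_mm = NULL,
                       grid_shape = c(48L, 48L, 48L),
                       spacing_mm = c(1, 1, 2.5), margin_mm = 3) {
  kind <- match.arg(kind)
  center_mm <- as.numeric(center_mm)
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(center_mm) == 3L, length(grid_shape) == 3L,
            all(grid_shape >= 1L), length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  if (kind == "ellipsoid") {
    radii_mm <- as.numeric(radii_mm)
    if (length(radii_mm) != 3L || any(radii_mm <= 0))
      stop("ellipsoid needs 3 positive `radii_mm`", call. = FALSE)
    extent <- radii_mm
  } else {
    if (is.null(radius_mm) || is.null(length_mm) || radius_mm <= 0 || length_mm <= 0)
      stop("tube needs positive `radius_mm` and `length_mm`", call. = FALSE)
    extent <- c(radius_mm, radius_mm, length_mm / 2)
  }
  # voxel centres span [0, (n-1)*spacing]; demand margin_mm clearance
  hi <- (grid_shape - 1) * spacing_mm
  if (any(center_mm - extent < margin_mm) ||
      any(center_mm + extent > hi - margin_mm))
    stop("shape does not fit inside the grid with ", margin_mm, " mm margin",
         call. = FALSE)
  structure(list(kind = kind, center_mm = center_mm, radii_mm = radii_mm,
                 radius_mm = radius_mm, length_mm = length_mm,
                 grid_shape = grid_shape, spacing_mm = spacing_mm,
                 margin_mm = margin_mm),
            class = "shape_spec")
}

#' Rasterize an analytic shape to a binary volume
#'
#' A voxel is foreground iff its centre lies inside the analytic shape.
#' Deterministic; the origin of the resulting volume is `c(0, 0, 0)`.
#'
#' @param shape A [shape_spec()].
#' @return A [binary_volume()].
#' @export
rasterize_shape <- function(shape) {
  stopifnot(inherits(shape, "shape_spec"))
  d <- shape$grid_shape
  sp <- shape$spacing_mm
  cx <- (seq_len(d[1]) - 1) * sp[1] - shape$center_mm[1]
  cy <- (seq_len(d[2]) - 1) * sp[2] - shape$center_mm[2]
  cz <- (seq_len(d[3]) - 1) * sp[3] - shape$center_mm[3]
  if (shape$kind == "ellipsoid") {
    r <- shape$radii_mm
    qx <- (cx / r[1])^2
    qy <- (cy / r[2])^2
    qz <- (cz / r[3])^2
    g <- outer(outer(qx, qy, "+"), qz, "+") <= 1
  } else {
    q2 <- outer(cx^2, cy^2, "+") <= shape$radius_mm^2
    inz <- abs(cz) <= shape$length_mm / 2
    g <- outer(q2, inz, "&")
  }
  binary_volume(array(g, dim = d), spacing_mm = sp)
}

#' Edit specifications
#'
#' Describe one editing operation applied to a DLAS contour to produce the
#' final approved contour:
#' \describe{
#'   \item{`edit_none()`}{bit-identical copy — the contour is used unedited.}
#'   \item{`edit_margin(margin_mm)`}{isotropic margin growth (positive) or
#'     shrinkage (negative) by a physical distance, via a Euclidean distance
#'     threshold — the kind of systematic change seen when a DLAS model is
#'     configured to grow a structure by a fixed margin.}
#'   \item{`edit_crop(crop_fraction, side)`}{removal of a contiguous
#'     superior or inferior fraction of the occupied z-extent — the
#'     characteristic edit of serial organs whose longitudinal extent is
#'     adjusted, and the failure mode where only part of a structure is
#'     contoured.}
#'   \item{`edit_bump(count, radius_mm, depth_mm)`}{`count` local spherical
#'     surface patches of lateral radius `radius_mm`, protruding
#'     (`depth_mm > 0`) or indenting (`depth_mm < 0`) by `|depth_mm|` —
#'     small local corrections.}
#' }
#'
#' @param margin_mm Signed margin in mm.
#' @param crop_fraction Fraction of occupied z-slices removed, in \[0, 1).
#' @param side `"random"`, `"inferior"` or `"superior"`: which end is
#'   removed. `"random"` draws per case.
#' @param count Number of surface patches.
#' @param radius_mm Patch sphere radius in mm.
#' @param depth_mm Signed patch depth in mm; `|depth_mm| <= radius_mm`.
#' @return An object of class `edit_spec`.
#' @name edit_spec
NULL

new_edit <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "edit_spec")
}

#' @rdname edit_spec
#' @export
edit_none <- function() new_edit("none")

#' @rdname edit_spec
#' @export
edit_margin <- function(margin_mm) {
  stopifnot(is.numeric(margin_mm), length(margin_mm) == 1L, margin_mm != 0)
  new_edit("margin", margin_mm = as.numeric(margin_mm))
}

#' @rdname edit_spec
#' @export
edit_crop <- function(crop_fraction, side = c("random", "inferior", "superior")) {
  stopifnot(is.numeric(crop_fraction), crop_fraction >= 0, crop_fraction < 1)
  new_edit("crop", crop_fraction = as.numeric(crop_fraction),
           side = match.arg(side))
}

#' @rdname edit_spec
#' @export
edit_bump <- function(count, radius_mm, depth_mm) {
  stopifnot(count >= 1, radius_mm > 0, depth_mm != 0,
            abs(depth_mm) <= radius_mm)
  new_edit("bump", count = as.integer(count), radius_mm = as.numeric(radius_mm),
           depth_mm = as.numeric(depth_mm))
}

#' Apply an edit to a structure mask
#'
#' Produces the "final approved" mask from a DLAS mask under one
#' [edit_spec]. Random choices (crop side when `"random"`, bump placement)
#' are drawn from R's current RNG stream, which the cohort generator seeds
#' per case; call `set.seed()` first for standalone reproducibility. An edit
#' may legitimately empty the mask (emulating deletion of a structure).
#'
#' @param mask A [binary_volume()].
#' @param edit An [edit_spec].
#' @return An edited [binary_volume()] on the same grid.
#' @export
apply_edit <- function(mask, edit) {
  stopifnot(inherits(mask, "binary_volume"), inherits(edit, "edit_spec"))
  switch(edit$kind,
    none = mask,
    margin = apply_margin(mask, edit$margin_mm),
    crop = apply_crop(mask, edit$crop_fraction, edit$side),
    bump = apply_bumps(mask, edit$count, edit$radius_mm, edit$depth_mm),
    stop("unknown edit kind: ", edit$kind, call. = FALSE)
  )
}

apply_margin <- function(mask, margin_mm) {
  d <- dim(mask$grid)
  m2 <- margin_mm^2
  if (margin_mm > 0) {
    if (!any(mask$grid)) return(mask)   # nothing to dilate
    d2 <- .sq_distance_transform(as.logical(mask$grid), as.integer(d),
                                 mask$spacing_mm)
    g <- array(d2 <= m2, dim = d)
  } else {
    if (all(mask$grid)) return(mask)
    d2 <- .sq_distance_transform(as.logical(!mask$grid), as.integer(d),
                                 mask$spacing_mm)
    g <- array(d2 > m2, dim = d) & mask$grid
  }
  binary_volume(g, mask$spacing_mm, mask$origin_mm)
}

apply_crop <- function(mask, crop_fraction, side) {
  g <- mask$grid
  occ <- which(apply(g, 3, any))
  if (length(occ) == 0 || crop_fraction == 0) return(mask)
  n_keep <- ceiling((1 - crop_fraction) * length(occ))
  if (side == "random") side <- if (stats::runif(1) < 0.5) "inferior" else "superior"
  kept <- if (side == "superior") utils::head(occ, n_keep) else utils::tail(occ, n_keep)
  drop <- setdiff(occ, kept)
  g[, , drop] <- FALSE
  binary_volume(g, mask$spacing_mm, mask$origin_mm)
}

apply_bumps <- function(mask, count, radius_mm, depth_mm) {
  surf <- extract_surface(mask)
  if (surf$count == 0) return(mask)
  d <- dim(mask$grid)
  sp <- mask$spacing_mm
  centroid <- colMeans(sweep(sweep(arrayInd(which(mask$grid), d) - 1, 2, sp, "*"),
                             2, mask$origin_mm, "+"))
  picks <- surf$positions_mm[sample.int(surf$count, min(count, surf$count),
                                        replace = FALSE), , drop = FALSE]
  g <- mask$grid
  depth <- min(abs(depth_mm), radius_mm)
  ax <- mask$origin_mm[1] + (seq_len(d[1]) - 1) * sp[1]
  ay <- mask$origin_mm[2] + (seq_len(d[2]) - 1) * sp[2]
  az <- mask$origin_mm[3] + (seq_len(d[3]) - 1) * sp[3]
  for (i in seq_len(nrow(picks))) {
    p <- picks[i, ]
    nrm <- p - centroid
    len <- sqrt(sum(nrm^2))
    nrm <- if (len < 1e-9) c(0, 0, 1) else nrm / len
    # sphere centred radius - depth beyond (add) or inside (carve) the
    # surface point: the patch protrudes/indents by `depth`
    ctr <- p + sign(depth_mm) * (radius_mm - depth) * nrm
    inside <- outer(outer((ax - ctr[1])^2, (ay - ctr[2])^2, "+"),
                    (az - ctr[3])^2, "+") <= radius_mm^2
    if (depth_mm > 0) g <- g | inside else g <- g & !inside
  }
  binary_volume(g, sp, mask$origin_mm)
}

#' Per-period editing distribution
#'
#' With probability `p_unedited` the final contour is a bit-identical copy of
#' the DLAS contour; otherwise one edit is drawn from the mixture `edits`
#' (probabilities conditional on being edited; must sum to 1).
#'
#' @param p_unedited Probability in \[0, 1\] the contour is used unedited.
#' @param edits List of `list(prob = , edit = edit_spec)` entries; may be
#'   empty iff `p_unedited == 1`.
#' @return An object of class `edit_distribution`.
#' @export
edit_distribution <- function(p_unedited, edits = list()) {
  stopifnot(is.numeric(p_unedited), p_unedited >= 0, p_unedited <= 1)
  if (length(edits) == 0) {
    if (p_unedited < 1)
      stop("`edits` may only be empty when p_unedited == 1", call. = FALSE)
  } else {
    probs <- vapply(edits, function(e) as.numeric(e$prob), numeric(1))
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
      stop("edit mixture probabilities must be >= 0 and sum to 1", call. = FALSE)
    ok <- vapply(edits, function(e) inherits(e$edit, "edit_spec"), logical(1))
    if (!all(ok)) stop("each mixture entry needs an `edit_spec`", call. = FALSE)
  }
  structure(list(p_unedited = as.numeric(p_unedited), edits = edits),
            class = "edit_distribution")
}

#' Synthetic cohort scenario
#'
#' A complete recipe for a synthetic audit cohort: how many periods and
#' patients, which OARs (each an analytic shape plus a per-period editing
#' distribution), the calendar anchoring, per-patient anatomical jitter, and
#' the master seed. With the seed fixed the generated cohort is
#' bit-reproducible, and each case's content depends only on its (period,
#' patient, OAR) coordinates — not on generation order — because per-case RNG
#' substreams are derived by counter-based mixing of the master seed.
#'
#' @param oar_defs Named list: OAR name to `list(shape = shape_spec,
#'   periods = list of edit_distribution)` with one distribution per period
#'   (a single distribution is recycled across periods).
#' @param n_periods Number of audit periods.
#' @param patients_per_period Patients accrued in each period.
#' @param seed Master seed (integer).
#' @param audit_start First day of period 0 (ISO-8601).
#' @param period_length_months Calendar months per period.
#' @param jitter_radii_frac,jitter_center_mm Per-patient uniform jitter of
#'   the base shape: relative on radii, absolute (mm) on centre. Jitter makes
#'   every patient's DLAS mask distinct, so unedited detection is exercised
#'   against genuinely different anatomies.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(oar_defs, n_periods, patients_per_period, seed,
                          audit_start = "2023-01-01",
                          period_length_months = 2L,
                          jitter_radii_frac = 0.05, jitter_center_mm = 2) {
  stopifnot(is.list(oar_defs), length(oar_defs) > 0, !is.null(names(oar_defs)))
  n_periods <- as.integer(n_periods)
  patients_per_period <- as.integer(patients_per_period)
  stopifnot(n_periods >= 1L, patients_per_period >= 1L)
  for (nm in names(oar_defs)) {
    def <- oar_defs[[nm]]
    if (!inherits(def$shape, "shape_spec"))
      stop("OAR '", nm, "' needs a `shape_spec`", call. = FALSE)
    per <- def$periods
    if (inherits(per, "edit_distribution")) per <- list(per)
    if (length(per) == 1L) per <- rep(per, n_periods)
    if (length(per) != n_periods ||
        !all(vapply(per, inherits, logical(1), "edit_distribution")))
      stop("OAR '", nm, "' needs 1 or n_periods edit_distributions", call. = FALSE)
    oar_defs[[nm]]$periods <- per
  }
  structure(list(oar_defs = oar_defs, n_periods = n_periods,
                 patients_per_period = patients_per_period,
                 seed = as.integer(seed),
                 audit_start = parse_iso_date(audit_start),
                 period_length_months = as.integer(period_length_months),
                 jitter_radii_frac = jitter_radii_frac,
                 jitter_center_mm = jitter_center_mm),
            class = "scenario_spec")
}

# counter-based substream derivation: the per-case seed is a deterministic
# hash of (master seed, period, patient, oar), so cohort content does not
# depend on generation order. Arithmetic stays below 2^53, exact in doubles.
mix_seed <- function(seed, ...) {
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (k in c(...)) {
    h <- (h * 48271 + (as.numeric(k) + 1) * 8191) %% 2147483647
  }
  as.integer(h)
}

add_months <- function(date, n) seq(date, by = paste(n, "months"), length.out = 2)[2]

period_window <- function(audit_start, period_length_months, p) {
  c(add_months(audit_start, p * period_length_months),
    add_months(audit_start, (p + 1) * period_length_months))
}

# jittered per-patient anatomy only has to stay inside the grid (margin 0):
# the base shape already satisfies the scenario margin and the jitter is small
jitter_shape <- function(shape, radii_frac, center_mm) {
  ctr <- shape$center_mm + stats::runif(3, -center_mm, center_mm)
  if (shape$kind == "ellipsoid") {
    r <- shape$radii_mm * stats::runif(3, 1 - radii_frac, 1 + radii_frac)
    shape_spec("ellipsoid", ctr, radii_mm = r, grid_shape = shape$grid_shape,
               spacing_mm = shape$spacing_mm, margin_mm = 0)
  } else {
    shape_spec("tube", ctr,
               radius_mm = shape$radius_mm * stats::runif(1, 1 - radii_frac, 1 + radii_frac),
               length_mm = shape$length_mm * stats::runif(1, 1 - radii_frac, 1 + radii_frac),
               grid_shape = shape$grid_shape, spacing_mm = shape$spacing_mm,
               margin_mm = 0)
  }
}

generate_case <- function(scenario, p, i, oar_name, oar_index) {
  def <- scenario$oar_defs[[oar_name]]
  set.seed(mix_seed(scenario$seed, p, i, oar_index))
  shp <- jitter_shape(def$shape, scenario$jitter_radii_frac,
                      scenario$jitter_center_mm)
  dlas <- rasterize_shape(shp)
  dist <- def$periods[[p + 1]]
  edited <- stats::runif(1) >= dist$p_unedited
  final <- if (!edited) dlas else {
    probs <- vapply(dist$edits, function(e) e$prob, numeric(1))
    pick <- dist$edits[[sample.int(length(probs), 1, prob = probs)]]$edit
    apply_edit(dlas, pick)
  }
  win <- period_window(scenario$audit_start, scenario$period_length_months, p)
  day <- win[1] + sample.int(as.integer(win[2] - win[1]), 1) - 1
  structure_pair(patient_id = sprintf("P%03d-%03d", p, i),
                 oar_name = oar_name, acquisition_date = day,
                 dlas = dlas, final = final)
}

#' Generate a synthetic cohort in memory
#'
#' Draws every (period, patient, OAR) case of a scenario and returns the
#' structure pairs without touching the filesystem; [generate_cohort()]
#' wraps this and writes NIfTI masks plus a manifest CSV.
#'
#' @param scenario A [scenario_spec()].
#' @return List with `pairs` (list of [structure_pair()]) and `meta` (tibble
#'   with `patient_id`, `date`, `oar_name`, `period_index`).
#' @export
generate_pairs <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  oar_names <- names(scenario$oar_defs)
  pairs <- list()
  meta <- list()
  n <- 0L
  for (p in seq_len(scenario$n_periods) - 1L) {
    for (i in seq_len(scenario$patients_per_period)) {
      for (j in seq_along(oar_names)) {
        n <- n + 1L
        pr <- generate_case(scenario, p, i, oar_names[j], j)
        pairs[[n]] <- pr
        meta[[n]] <- tibble::tibble(patient_id = pr$patient_id,
                                    date = pr$acquisition_date,
                                    oar_name = pr$oar_name,
                                    period_index = p)
      }
    }
  }
  list(pairs = pairs, meta = dplyr::bind_rows(meta))
}

#' Generate a synthetic cohort on disk
#'
#' Materializes a scenario as NIfTI mask pairs plus a `manifest.csv` in the
#' same five-column format [load_manifest()] reads. Identical seeds produce
#' bit-identical mask files and manifest.
#'
#' @param scenario A [scenario_spec()].
#' @param out_dir Output directory (created if needed); masks go to
#'   `out_dir/masks/`.
#' @param compress Write `.nii.gz` (default) or plain `.nii`.
#' @return The manifest tibble (invisibly); `manifest.csv` and masks are on
#'   disk.
#' @export
generate_cohort <- function(scenario, out_dir, compress = TRUE) {
  stopifnot(inherits(scenario, "scenario_spec"))
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(mask_dir))
    stop("cannot create output directory ", mask_dir, call. = FALSE)
  gen <- generate_pairs(scenario)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- vector("list", length(gen$pairs))
  for (n in seq_along(gen$pairs)) {
    pr <- gen$pairs[[n]]
    stem <- sprintf("%s_%s", pr$patient_id,
                    normalize_structure_name(pr$oar_name))
    dlas_rel <- file.path("masks", paste0(stem, "_dlas", ext))
    final_rel <- file.path("masks", paste0(stem, "_final", ext))
    write_mask(pr$dlas, file.path(out_dir, dlas_rel))
    write_mask(pr$final, file.path(out_dir, final_rel))
    rows[[n]] <- tibble::tibble(patient_id = pr$patient_id,
                                date = format(pr$acquisition_date),
                                oar_name = pr$oar_name,
                                dlas_path = dlas_rel,
                                final_path = final_rel)
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                   progress = FALSE)
  invisible(manifest)
}
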