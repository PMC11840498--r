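test_that("rasterize_shape matches analytic volumes and symmetries", {
  # 5 mm sphere at 1 mm spacing: voxel count within 10% of (4/3) pi r^3
  sph <- shape_spec("ellipsoid", center_mm = c(10, 10, 10),
                    radii_mm = c(5, 5, 5), grid_shape = c(21L, 21L, 21L),
                    spacing_mm = c(1, 1, 1))
  v <- rasterize_shape(sph)
  expect_lt(abs(n_foreground(v) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)

  # tube: every occupied z-slice has the same cross-section
  tb <- shape_spec("tube", center_mm = c(12, 12, 25), radius_mm = 4,
                   length_mm = 40, grid_shape = c(25L, 25L, 51L),
                   spacing_mm = c(1, 1, 1))
  tube <- rasterize_shape(tb)
  occ <- which(apply(tube$grid, 3, any))
  sections <- apply(tube$grid[, , occ], 3, identity)
  expect_true(all(apply(sections, 2, identical, sections[, 1])))
  expect_equal(length(occ), 41)  # 40 mm length inclusive of both end slices

  # sub-voxel shape centred on a voxel centre: exactly one voxel
  tiny <- shape_spec("ellipsoid", center_mm = c(10, 10, 10),
                     radii_mm = c(0.4, 0.4, 0.4), grid_shape = c(21L, 21L, 21L),
                     spacing_mm = c(1, 1, 1), margin_mm = 3)
  expect_equal(n_foreground(rasterize_shape(tiny)), 1)

  expect_error(shape_spec("ellipsoid", center_mm = c(3, 10, 10),
                          radii_mm = c(5, 5, 5), grid_shape = c(21L, 21L, 21L),
                          spacing_mm = c(1, 1, 1)), "fit")
})

test_that("margin edits are exact Euclidean morphology", {
  tb <- shape_spec("tube", center_mm = c(12, 12, 25), radius_mm = 4,
                   length_mm = 30, grid_shape = c(25L, 25L, 51L),
                   spacing_mm = c(1, 1, 1))
  tube <- rasterize_shape(tb)
  grown <- apply_edit(tube, edit_margin(1))
  expect_gt(n_foreground(grown), n_foreground(tube))
  expect_true(all(tube$grid[grown$grid == FALSE] == FALSE))  # superset
  # 1 mm growth is invisible at 3 mm tolerance, visible at 0.5 mm
  expect_equal(surface_dice(tube, grown, 3), 1.0)
  expect_lt(surface_dice(tube, grown, 0.5), 1.0)
  expect_equal(surface_dice(tube, grown, 0.5),
               oracle_surface_dice(tube, grown, 0.5))

  shrunk <- apply_edit(tube, edit_margin(-1))
  expect_lt(n_foreground(shrunk), n_foreground(tube))
  expect_true(all(shrunk$grid[tube$grid == FALSE] == FALSE))  # subset
  # erosion then comparison respects the same tolerance logic
  expect_equal(surface_dice(tube, shrunk, 3), 1.0)
})

test_that("increasing margin magnitude never increases sDSC against the original", {
  tb <- shape_spec("ellipsoid", center_mm = c(16, 16, 40),
                   radii_mm = c(9, 8, 20), grid_shape = c(33L, 33L, 33L),
                   spacing_mm = c(1, 1, 2.5))
  base <- rasterize_shape(tb)
  for (tol in c(1, 3)) {
    vals <- vapply(c(1, 2, 4, 6),
                   function(m) surface_dice(base, apply_edit(base, edit_margin(m)), tol),
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("crop edits remove a contiguous z-extent of the requested size", {
  tb <- shape_spec("tube", center_mm = c(12, 12, 25), radius_mm = 4,
                   length_mm = 40, grid_shape = c(25L, 25L, 51L),
                   spacing_mm = c(1, 1, 1))
  tube <- rasterize_shape(tb)
  occ <- function(v) which(apply(v$grid, 3, any))
  n0 <- length(occ(tube))
  per_slice <- n_foreground(tube) / n0

  set.seed(1)
  cropped <- apply_edit(tube, edit_crop(0.5))
  # about half the foreground remains, within one slice
  expect_lt(abs(n_foreground(cropped) - 0.5 * n_foreground(tube)), per_slice + 1)
  expect_equal(diff(range(occ(cropped))) + 1, length(occ(cropped)))  # contiguous

  inf <- apply_edit(tube, edit_crop(0.25, side = "superior"))
  expect_equal(occ(inf), utils::head(occ(tube), ceiling(0.75 * n0)))
  sup <- apply_edit(tube, edit_crop(0.25, side = "inferior"))
  expect_equal(occ(sup), utils::tail(occ(tube), ceiling(0.75 * n0)))
})

test_that("bump edits modify the surface locally by the requested depth", {
  sph <- shape_spec("ellipsoid", center_mm = c(16, 16, 16),
                    radii_mm = c(9, 9, 9), grid_shape = c(33L, 33L, 33L),
                    spacing_mm = c(1, 1, 1))
  base <- rasterize_shape(sph)
  set.seed(42)
  out <- apply_edit(base, edit_bump(2, radius_mm = 4, depth_mm = 4))
  expect_gt(n_foreground(out), n_foreground(base))
  expect_false(is_geometrically_identical(base, out))
  # protrusion depth 4 mm: beyond a 3 mm tolerance but within 5 mm
  expect_lt(surface_dice(base, out, 3), 1.0)
  expect_equal(surface_dice(base, out, 5), 1.0)

  set.seed(42)
  carved <- apply_edit(base, edit_bump(2, radius_mm = 4, depth_mm = -4))
  expect_lt(n_foreground(carved), n_foreground(base))
})

test_that("edit none is bit-identical and empty-result edits are allowed", {
  v <- make_cube()
  expect_true(is_geometrically_identical(v, apply_edit(v, edit_none())))
  emptied <- apply_edit(make_cube(c(8L, 8L, 8L), 3L, 2L), edit_margin(-5))
  expect_equal(n_foreground(emptied), 0)
})

test_that("generated cohorts are seed-reproducible and order-independent", {
  sc <- scenario_preset("steady_state", seed = 9, n_periods = 2,
                        patients_per_period = 3, grid_shape = c(20L, 20L, 20L))
  g1 <- generate_pairs(sc)
  g2 <- generate_pairs(sc)
  expect_identical(g1$meta, g2$meta)
  expect_identical(g1$pairs[[5]]$final$grid, g2$pairs[[5]]$final$grid)

  # different seed changes content
  sc2 <- scenario_preset("steady_state", seed = 10, n_periods = 2,
                         patients_per_period = 3, grid_shape = c(20L, 20L, 20L))
  g3 <- generate_pairs(sc2)
  expect_false(identical(g1$meta$date, g3$meta$date))

  # on-disk cohorts are bit-identical across runs with the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(sc, d1)
  generate_cohort(sc, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("degenerate all-unedited scenario audits as 100% unedited", {
  defs <- list(organ = list(
    shape = shape_spec("ellipsoid", c(10, 10, 10), radii_mm = c(4, 4, 4),
                       grid_shape = c(21L, 21L, 21L), spacing_mm = c(1, 1, 1)),
    periods = edit_distribution(1)))
  sc <- scenario_spec(defs, n_periods = 2, patients_per_period = 4, seed = 2)
  ev <- evaluate_cohort(generate_pairs(sc)$pairs, preset_audit_config(sc))
  s <- summarize_periods(ev$results)
  expect_true(all(s$pct_unedited == 100))
  expect_true(all(s$mean_sdsc == 1))
})

test_that("generated dates fall inside their period windows", {
  sc <- scenario_preset("steady_state", seed = 4, n_periods = 3,
                        patients_per_period = 4, grid_shape = c(20L, 20L, 20L))
  g <- generate_pairs(sc)
  cfg <- preset_audit_config(sc)
  expect_identical(as.integer(assign_period(g$meta$date, cfg)),
                   as.integer(g$meta$period_index))
})

test_that("scenario validation rejects bad mixtures and missing shapes", {
  expect_error(edit_distribution(0.5), "empty")
  expect_error(edit_distribution(0.5, list(list(prob = 0.5, edit = edit_margin(1)))),
               "sum to 1")
  expect_error(scenario_spec(list(), 1, 1, 1), "length")
  expect_error(
    scenario_spec(list(o = list(shape = "not a shape",
                                periods = edit_distribution(1))), 1, 1, 1),
    "shape_spec")
})
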