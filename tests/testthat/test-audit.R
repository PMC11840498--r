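test_that("assign_period bins dates into calendar-month blocks", {
  cfg <- tiny_config()
  expect_equal(assign_period("2023-01-01", cfg), 0)
  expect_equal(assign_period("2023-02-28", cfg), 0)
  expect_equal(assign_period("2023-03-01", cfg), 1)  # boundary -> later block
  expect_equal(assign_period("2023-12-31", cfg), 5)
  expect_error(assign_period("2022-12-31", cfg), "before audit start")

  # 18 months of dates at 2-month periods span exactly 9 periods (0..8)
  days <- seq(as.Date("2023-01-01"), as.Date("2024-06-30"), by = "day")
  idx <- assign_period(days, cfg)
  expect_equal(sort(unique(idx)), 0:8)

  # month arithmetic is calendar-based, not 30-day blocks
  cfg3 <- audit_config("Bladder", audit_start = "2023-01-31",
                       period_length_months = 1L)
  expect_equal(assign_period("2023-02-28", cfg3), 0)
  expect_equal(assign_period("2023-03-31", cfg3), 2)
})

test_that("evaluate_pair combines sDSC, identity and period assignment", {
  cfg <- tiny_config()
  cube <- make_cube(c(12L, 12L, 12L), 4L, 5L)
  pair <- structure_pair("P1", "Bladder", "2023-05-10", cube, cube)
  r <- evaluate_pair(pair, cfg)
  expect_equal(r$sdsc, 1.0)
  expect_true(r$unedited)
  expect_equal(r$period_index, 2)
  expect_equal(r$tolerance_mm, 3)

  # one flipped voxel on the border: edited, but within the 3 mm tolerance
  edited <- cube
  edited$grid[4, 4, 4] <- FALSE
  r2 <- evaluate_pair(structure_pair("P1", "Bladder", "2023-05-10", cube, edited), cfg)
  expect_false(r2$unedited)
  expect_equal(r2$sdsc, 1.0)

  # deletion: final empty while DLAS non-empty is maximal editing
  r3 <- evaluate_pair(structure_pair("P1", "Bladder", "2023-05-10", cube,
                                     empty_volume(c(12L, 12L, 12L))), cfg)
  expect_equal(r3$sdsc, 0.0)
  expect_false(r3$unedited)

  # per-OAR tolerance override is honoured
  r4 <- evaluate_pair(structure_pair("P1", "SpinalCord", "2023-01-10", cube, cube), cfg)
  expect_equal(r4$tolerance_mm, 2)
})

test_that("summarize_periods computes per-cell census statistics", {
  res <- make_results("Bladder", sdsc = c(1, 1, 0.9, 0.8),
                      unedited = c(TRUE, TRUE, FALSE, FALSE))
  s <- summarize_period(res, "Bladder", 0)
  expect_equal(s$n, 4)
  expect_equal(s$pct_unedited, 50)
  expect_equal(s$mean_sdsc, 0.925)
  expect_equal(s$min_sdsc, 0.8)
  expect_equal(s$max_sdsc, 1.0)
  expect_equal(s$sd_sdsc, sqrt(mean((c(1, 1, 0.9, 0.8) - 0.925)^2)))  # divisor n

  s1 <- summarize_periods(make_results("Bladder", sdsc = 0.97))
  expect_equal(s1$n, 1)
  expect_equal(s1$pct_unedited, 0)
  expect_equal(s1$sd_sdsc, 0)

  all_unedited <- make_results("Bladder", sdsc = rep(1, 10),
                               unedited = rep(TRUE, 10))
  s2 <- summarize_periods(all_unedited)
  expect_equal(s2$pct_unedited, 100)
  expect_equal(s2$mean_sdsc, 1)
  expect_equal(s2$sd_sdsc, 0)

  expect_error(summarize_period(res, "Bladder", 7), "no results")
})

test_that("cell counts conserve the number of evaluated results", {
  set.seed(11)
  res <- dplyr::bind_rows(
    make_results("Bladder", runif(7), period = sample(0:2, 7, TRUE)),
    make_results("SpinalCord", runif(5), period = sample(0:2, 5, TRUE))
  )
  s <- summarize_periods(res)
  expect_equal(sum(s$n), nrow(res))
  # pct_unedited == 100 iff every result in the cell is unedited
  expect_true(all((s$pct_unedited == 100) ==
                  tapply(res$unedited,
                         interaction(res$oar_name, res$period_index, drop = TRUE),
                         all)[paste(s$oar_name, s$period_index, sep = ".")]))
})

test_that("summarize_overall aggregates per-OAR means unweighted", {
  ps <- dplyr::bind_rows(
    summarize_periods(make_results("A", c(0.9, 0.9))),
    summarize_periods(make_results("B", c(1.0, 1.0),
                                   unedited = c(TRUE, TRUE)))
  )
  ov <- summarize_overall(ps)
  expect_equal(ov$mean_sdsc, 0.95)
  expect_equal(ov$min_sdsc, 0.9)
  expect_equal(ov$max_sdsc, 1.0)
  expect_equal(ov$min_pct_unedited, 0)
  expect_equal(ov$max_pct_unedited, 100)

  # exclusion reduces to the remaining OAR; empty exclusion is the identity
  expect_equal(summarize_overall(ps, exclude_oars = "A")$mean_sdsc, 1.0)
  expect_identical(summarize_overall(ps, exclude_oars = character()), ov)
  expect_error(summarize_overall(ps, exclude_oars = c("A", "B")), "no period")

  # roi weighting pools over cases instead
  ps2 <- dplyr::bind_rows(
    summarize_periods(make_results("A", rep(0.8, 3))),
    summarize_periods(make_results("B", 1.0))
  )
  expect_equal(summarize_overall(ps2, weight = "roi")$mean_sdsc,
               (3 * 0.8 + 1) / 4)
})

test_that("flag_outliers applies the one-sided mean - k*sd rule", {
  cfg <- tiny_config(outlier_k = 2, min_n_for_outlier = 5)
  sdscs <- c(rep(0.98, 8), 0.95, 0.60)
  res <- make_results("Bladder", sdscs)
  out <- flag_outliers(res, cfg)
  m <- mean(sdscs)
  s <- sqrt(mean((sdscs - m)^2))
  expect_equal(nrow(out$flags), 1)
  expect_equal(out$flags$patient_id, "P10")
  expect_equal(out$flags$sdsc, 0.60)
  expect_equal(out$flags$threshold, m - 2 * s)
  expect_lt(out$flags$sdsc, out$flags$threshold)

  # degenerate spread yields no flags; small OARs are skipped and reported
  res0 <- make_results("Bladder", rep(0.9, 6))
  expect_equal(nrow(flag_outliers(res0, cfg)$flags), 0)
  small <- make_results("SpinalCord", c(0.9, 0.1))
  out2 <- flag_outliers(small, cfg)
  expect_equal(nrow(out2$flags), 0)
  expect_equal(out2$skipped$oar_name, "SpinalCord")
})

test_that("flag_outliers output is invariant to input order", {
  set.seed(5)
  res <- dplyr::bind_rows(
    make_results("Bladder", c(runif(10, 0.9, 1), 0.2)),
    make_results("SpinalCord", c(runif(8, 0.95, 1), 0.3))
  )
  cfg <- tiny_config()
  shuffled <- res[sample.int(nrow(res)), ]
  expect_identical(flag_outliers(res, cfg)$flags,
                   flag_outliers(shuffled, cfg)$flags)
})

test_that("trend_series orders periods and handles absent OARs", {
  ps <- dplyr::bind_rows(
    summarize_periods(make_results("A", c(0.9), period = 2L)),
    summarize_periods(make_results("A", c(0.8), period = 0L)),
    summarize_periods(make_results("A", c(0.85), period = 1L))
  )
  tr <- trend_series(ps, "A")
  expect_equal(tr$period_index, 0:2)
  expect_equal(tr$mean_sdsc, c(0.8, 0.85, 0.9))
  expect_gt(trend_slope(tr), 0)
  expect_equal(nrow(trend_series(ps, "Missing")), 0)
  expect_true(is.na(trend_slope(trend_series(ps, "Missing"))))
})
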