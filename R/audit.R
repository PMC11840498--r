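#' Assign a date to an audit period
#'
#' Periods are consecutive blocks of `period_length_months` calendar months
#' anchored at the audit start date; a date on a block boundary belongs to
#' the later block. An 18-month audit at 2-month periods therefore spans
#' indices 0 to 8 — nine consecutive periods.
#'
#' @param date A `Date` (or ISO-8601 string), on or after the audit start.
#' @param config An [audit_config()].
#' @return Non-negative integer period index (vectorised over `date`).
#' @examples
#' cfg <- audit_config("Bladder", audit_start = "2023-01-01")
#' assign_period("2023-01-01", cfg)  # 0
#' assign_period("2023-03-01", cfg)  # 1
#' @export
assign_period <- function(date, config) {
  stopifnot(inherits(config, "audit_config"))
  date <- parse_iso_date(date)
  start <- config$audit_start
  if (any(date < start))
    stop("date before audit start (", format(start), "): ",
         paste(format(date[date < start]), collapse = ", "), call. = FALSE)
  sl <- as.POSIXlt(start)
  dl <- as.POSIXlt(date)
  months <- 12L * (dl$year - sl$year) + (dl$mon - sl$mon) -
    as.integer(dl$mday < sl$mday)
  months %/% config$period_length_months
}

#' Evaluate one structure pair
#'
#' Computes the surface Dice at the OAR's configured tolerance, tests for
#' voxel-exact identity (contour used unedited), and assigns the audit
#' period.
#'
#' @param pair A [structure_pair()].
#' @param config An [audit_config()].
#' @return A one-row tibble with columns `patient_id`, `oar_name`, `date`,
#'   `period_index`, `sdsc`, `unedited`, `tolerance_mm`.
#' @export
evaluate_pair <- function(pair, config) {
  stopifnot(inherits(pair, "structure_pair"), inherits(config, "audit_config"))
  tol <- oar_tolerance(pair$oar_name, config)
  unedited <- is_geometrically_identical(pair$dlas, pair$final)
  sdsc <- if (unedited) 1 else surface_dice(pair$dlas, pair$final, tol)
  tibble::tibble(
    patient_id = pair$patient_id,
    oar_name = pair$oar_name,
    date = pair$acquisition_date,
    period_index = assign_period(pair$acquisition_date, config),
    sdsc = sdsc,
    unedited = unedited,
    tolerance_mm = tol
  )
}

#' Evaluate a whole cohort
#'
#' Runs [evaluate_pair()] over every resolved pair of a manifest (or a plain
#' list of `structure_pair`s). Pairs that fail evaluation are excluded from
#' the results and returned with a reason, so downstream statistics only
#' cover successful comparisons and the failure rate stays visible.
#'
#' @param cohort A `cohort_manifest` from [load_manifest()] /
#'   [generate_cohort()], or a list of [structure_pair()] objects.
#' @param config An [audit_config()].
#' @return List with `results` (tibble, one row per evaluated pair) and
#'   `failures` (tibble of pair identifiers with a `reason` column; includes
#'   the manifest's unresolved rows when a manifest is supplied).
#' @export
evaluate_cohort <- function(cohort, config) {
  stopifnot(inherits(config, "audit_config"))
  if (inherits(cohort, "cohort_manifest")) {
    pairs <- cohort$pairs
    pre_failures <- cohort$unresolved[, c("patient_id", "oar_name", "reason")]
  } else {
    pairs <- cohort
    pre_failures <- tibble::tibble(patient_id = character(),
                                   oar_name = character(),
                                   reason = character())
  }
  rows <- vector("list", length(pairs))
  fail <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    res <- tryCatch(evaluate_pair(pairs[[i]], config), error = function(e) e)
    if (inherits(res, "error")) {
      fail[[i]] <- tibble::tibble(patient_id = pairs[[i]]$patient_id,
                                  oar_name = pairs[[i]]$oar_name,
                                  reason = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  results <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(pre_failures, dplyr::bind_rows(fail))
  list(results = results, failures = failures)
}

# population SD: descriptive statistic over the census of a period's cases
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Summarize results per OAR per period
#'
#' One row per (OAR, period) cell that has at least one result: count,
#' percentage of unedited contours, and mean / SD / min / max of the surface
#' Dice. SD is the population SD (divisor n), describing the census of the
#' period's cases; a single-result cell reports SD 0. Cells with no results
#' are absent, not zero-filled.
#'
#' @param results Results tibble from [evaluate_cohort()].
#' @return Tibble with columns `oar_name`, `period_index`, `n`,
#'   `pct_unedited`, `mean_sdsc`, `sd_sdsc`, `min_sdsc`, `max_sdsc`.
#' @export
summarize_periods <- function(results) {
  stopifnot(is.data.frame(results))
  results |>
    dplyr::group_by(.data$oar_name, .data$period_index) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_unedited = 100 * mean(.data$unedited),
      mean_sdsc = mean(.data$sdsc),
      sd_sdsc = sd_pop(.data$sdsc),
      min_sdsc = min(.data$sdsc),
      max_sdsc = max(.data$sdsc),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$oar_name, .data$period_index)
}

#' Summarize one (OAR, period) cell
#'
#' @inheritParams summarize_periods
#' @param oar_name,period_index The cell to summarize.
#' @return One-row tibble as in [summarize_periods()]; errors if the cell is
#'   empty.
#' @export
summarize_period <- function(results, oar_name, period_index) {
  sub <- results[results$oar_name == oar_name &
                   results$period_index == period_index, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no results for OAR '", oar_name, "' in period ", period_index,
         call. = FALSE)
  summarize_periods(sub)
}

#' Summarize all-time per-OAR totals
#'
#' The audit's headline table: per OAR pooled over all periods — total ROIs,
#' % unedited, mean and SD of sDSC.
#'
#' @inheritParams summarize_periods
#' @return Tibble with columns `oar_name`, `total_rois`, `pct_unedited`,
#'   `mean_sdsc`, `sd_sdsc`.
#' @export
summarize_oars <- function(results) {
  stopifnot(is.data.frame(results))
  results |>
    dplyr::group_by(.data$oar_name) |>
    dplyr::summarise(
      total_rois = dplyr::n(),
      pct_unedited = 100 * mean(.data$unedited),
      mean_sdsc = mean(.data$sdsc),
      sd_sdsc = sd_pop(.data$sdsc),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$oar_name)
}

#' Cross-OAR summary per period
#'
#' For each period, unweighted statistics over the per-OAR mean sDSC values
#' (mean, SD, min–max range) and over the per-OAR unedited percentages (mean
#' and range). Aggregating at OAR level rather than pooling ROIs keeps
#' frequent OARs from dominating; the per-ROI pooled alternative is available
#' via `weight = "roi"`.
#'
#' @param period_summaries Tibble from [summarize_periods()].
#' @param exclude_oars Character vector of OAR names to drop before
#'   aggregation (e.g. OARs whose contouring practice changed mid-audit).
#' @param weight `"oar"` (default): unweighted over per-OAR means;
#'   `"roi"`: per-OAR means weighted by cell n, i.e. pooled over ROIs.
#' @return Tibble with one row per period: `period_index`, `n_oars`,
#'   `n_rois`, `mean_sdsc`, `sd_sdsc`, `min_sdsc`, `max_sdsc`,
#'   `pct_unedited`, `min_pct_unedited`, `max_pct_unedited` (sdsc columns
#'   describe the distribution of per-OAR means).
#' @export
summarize_overall <- function(period_summaries, exclude_oars = character(),
                              weight = c("oar", "roi")) {
  stopifnot(is.data.frame(period_summaries))
  weight <- match.arg(weight)
  kept <- period_summaries[!(period_summaries$oar_name %in% exclude_oars), ,
                           drop = FALSE]
  if (nrow(kept) == 0)
    stop("no period summaries left after exclusions", call. = FALSE)
  kept |>
    dplyr::group_by(.data$period_index) |>
    dplyr::summarise(
      n_oars = dplyr::n(),
      n_rois = sum(.data$n),
      # aggregates of the per-OAR means computed before the names are reused
      sd_sdsc = sd_pop(.data$mean_sdsc),
      min_sdsc = min(.data$mean_sdsc),
      max_sdsc = max(.data$mean_sdsc),
      min_pct_unedited = min(.data$pct_unedited),
      max_pct_unedited = max(.data$pct_unedited),
      mean_sdsc = if (weight == "oar") mean(.data$mean_sdsc)
                  else sum(.data$mean_sdsc * .data$n) / sum(.data$n),
      pct_unedited = if (weight == "oar") mean(.data$pct_unedited)
                     else sum(.data$pct_unedited * .data$n) / sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::select("period_index", "n_oars", "n_rois", "mean_sdsc", "sd_sdsc",
                  "min_sdsc", "max_sdsc", "pct_unedited",
                  "min_pct_unedited", "max_pct_unedited") |>
    dplyr::arrange(.data$period_index)
}

#' Flag outlier cases
#'
#' For each OAR with at least `min_n_for_outlier` results across all
#' periods, flags every case whose sDSC falls below
#' `mean - k * sd` of that OAR's full result set. The rule is one-sided:
#' unusually heavy editing (low sDSC) is the anomaly worth investigating;
#' unusually light editing is not. OARs with too few results are skipped and
#' reported, and an OAR whose results are all identical (zero spread) yields
#' no flags. Output order is deterministic: by OAR name, then patient id.
#'
#' @inheritParams summarize_periods
#' @param config An [audit_config()] supplying `outlier_k` and
#'   `min_n_for_outlier`.
#' @return List with `flags` (tibble: `patient_id`, `oar_name`,
#'   `period_index`, `sdsc`, `oar_mean`, `oar_sd`, `threshold`) and
#'   `skipped` (tibble of OARs below the minimum n).
#' @export
flag_outliers <- function(results, config) {
  stopifnot(is.data.frame(results), inherits(config, "audit_config"))
  k <- config$outlier_k
  stats <- results |>
    dplyr::group_by(.data$oar_name) |>
    dplyr::summarise(n = dplyr::n(),
                     oar_mean = mean(.data$sdsc),
                     oar_sd = sd_pop(.data$sdsc),
                     .groups = "drop")
  skipped <- stats[stats$n < config$min_n_for_outlier,
                   c("oar_name", "n"), drop = FALSE]
  eligible <- stats[stats$n >= config$min_n_for_outlier, , drop = FALSE]
  flags <- results |>
    dplyr::inner_join(eligible, by = "oar_name") |>
    dplyr::mutate(threshold = .data$oar_mean - k * .data$oar_sd) |>
    dplyr::filter(.data$sdsc < .data$threshold) |>
    dplyr::select("patient_id", "oar_name", "period_index", "sdsc",
                  "oar_mean", "oar_sd", "threshold") |>
    dplyr::arrange(.data$oar_name, .data$patient_id)
  list(flags = flags, skipped = tibble::as_tibble(skipped))
}

#' Trend series for one OAR
#'
#' The per-period mean sDSC and unedited percentage for one OAR, ordered by
#' period; periods with no cases are simply absent.
#'
#' @param period_summaries Tibble from [summarize_periods()].
#' @param oar_name OAR to extract.
#' @return Tibble with `period_index`, `mean_sdsc`, `pct_unedited`, sorted
#'   ascending by period.
#' @export
trend_series <- function(period_summaries, oar_name) {
  stopifnot(is.data.frame(period_summaries))
  period_summaries[period_summaries$oar_name == oar_name, , drop = FALSE] |>
    dplyr::arrange(.data$period_index) |>
    dplyr::select("period_index", "mean_sdsc", "pct_unedited")
}

#' Least-squares slope of a trend series
#'
#' Slope of `mean_sdsc` against `period_index`; a positive slope indicates
#' decreasing editing over the audit. Returns `NA` for fewer than two
#' periods.
#'
#' @param series Tibble from [trend_series()] or [summarize_overall()], with
#'   `period_index` and `mean_sdsc` columns.
#' @return Numeric slope (sDSC units per period).
#' @export
trend_slope <- function(series) {
  stopifnot(is.data.frame(series))
  if (nrow(series) < 2) return(NA_real_)
  stats::coef(stats::lm(mean_sdsc ~ period_index, data = series))[["period_index"]]
}
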