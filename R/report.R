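#' Assemble a full audit report
#'
#' Bundles every output shape of the audit: per-(OAR, period) summaries, the
#' all-time per-OAR table (total ROIs, % unedited, mean and SD sDSC),
#' cross-OAR per-period trend rows, outlier flags, and the unresolved /
#' failed entries with the overall failure rate.
#'
#' @param evaluation List from [evaluate_cohort()].
#' @param config An [audit_config()].
#' @param exclude_oars OARs excluded from the cross-OAR trend only (e.g.
#'   OARs whose contouring practice changed mid-audit); per-OAR tables always
#'   cover all OARs.
#' @return An object of class `audit_report`: list with `per_cell`,
#'   `per_oar_alltime`, `overall_by_period`, `outliers`, `skipped_oars`,
#'   `failures`, `failure_rate`, `n_results`.
#' @export
audit_report <- function(evaluation, config, exclude_oars = character()) {
  stopifnot(is.list(evaluation), is.data.frame(evaluation$results),
            inherits(config, "audit_config"))
  results <- evaluation$results
  failures <- evaluation$failures %||%
    tibble::tibble(patient_id = character(), oar_name = character(),
                   reason = character())
  if (nrow(results) == 0)
    stop("no evaluable structure pairs: nothing to audit", call. = FALSE)
  per_cell <- summarize_periods(results)
  out <- flag_outliers(results, config)
  n_total <- nrow(results) + nrow(failures)
  structure(list(
    per_cell = per_cell,
    per_oar_alltime = summarize_oars(results),
    overall_by_period = summarize_overall(per_cell, exclude_oars = exclude_oars),
    outliers = out$flags,
    skipped_oars = out$skipped,
    failures = failures,
    failure_rate = if (n_total == 0) 0 else nrow(failures) / n_total,
    n_results = nrow(results),
    exclude_oars = exclude_oars
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf(paste0("<audit_report> %d results over %d OARs and %d periods; ",
                     "%d outliers; failure rate %.1f%%\n"),
              x$n_results, nrow(x$per_oar_alltime),
              length(unique(x$per_cell$period_index)),
              nrow(x$outliers), 100 * x$failure_rate))
  invisible(x)
}

#' Write an audit report as CSV files
#'
#' Writes `summary_by_oar.csv`, `summary_by_period.csv`,
#' `overall_trend.csv`, `outliers.csv` and `failures.csv` (UTF-8, header
#' row, '.' decimal; percentages as numbers in \[0, 100\]). Output is
#' deterministic: the same report writes byte-identical files.
#'
#' @param report An [audit_report()].
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_audit_report <- function(report, out_dir) {
  stopifnot(inherits(report, "audit_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_csv(df, file.path(out_dir, name),
                                           progress = FALSE)
  w(report$per_oar_alltime, "summary_by_oar.csv")
  w(report$per_cell, "summary_by_period.csv")
  w(report$overall_by_period, "overall_trend.csv")
  w(report$outliers, "outliers.csv")
  w(report$failures, "failures.csv")
  invisible(out_dir)
}

#' Run the full audit from files
#'
#' The end-to-end pipeline: load the manifest, evaluate every resolvable
#' pair (surface Dice at the configured tolerance, unedited detection,
#' period assignment), aggregate, flag outliers, and write the report CSVs.
#' A run log (config echo, counts, failure rate) goes to `stderr`; rows that
#' fail to resolve are recorded, not fatal.
#'
#' @param manifest_path Cohort manifest CSV/JSON (see [load_manifest()]).
#' @param config Path to a YAML config, or an [audit_config()].
#' @param out_dir Directory for the report CSVs.
#' @param exclude_oars OARs excluded from the cross-OAR trend.
#' @param outlier_k Optional override of the config's outlier threshold.
#' @param quiet Suppress the run log.
#' @return The [audit_report()], invisibly.
#' @export
run_audit <- function(manifest_path, config, out_dir,
                      exclude_oars = character(), outlier_k = NULL,
                      quiet = FALSE) {
  if (!inherits(config, "audit_config")) config <- read_audit_config(config)
  if (!is.null(outlier_k)) config$outlier_k <- as.numeric(outlier_k)
  log <- function(...) if (!quiet) message(...)
  log("audit: ", length(config$protocol_oars), " protocol OARs, start ",
      format(config$audit_start), ", ", config$period_length_months,
      "-month periods, outlier k = ", config$outlier_k)
  manifest <- load_manifest(manifest_path, config)
  log("audit: ", nrow(manifest$entries), " resolved entries, ",
      nrow(manifest$unresolved), " unresolved (",
      sprintf("%.1f", 100 * failure_rate(manifest)), "% failure rate)")
  evaluation <- evaluate_cohort(manifest, config)
  report <- audit_report(evaluation, config, exclude_oars = exclude_oars)
  write_audit_report(report, out_dir)
  log("audit: ", report$n_results, " pairs evaluated, ",
      nrow(report$outliers), " outliers flagged; report written to ", out_dir)
  invisible(report)
}

#' Materialize a synthetic cohort from a scenario file
#'
#' Reads a YAML scenario file and writes the cohort (NIfTI masks and
#' manifest) with [generate_cohort()]. The file names a preset and may
#' override its knobs:
#' ```yaml
#' preset: drift
#' seed: 7
#' n_periods: 9
#' patients_per_period: 20
#' grid_shape: [48, 48, 48]
#' spacing_mm: [1, 1, 2.5]
#' ```
#'
#' @param scenario Path to a scenario YAML file, or a [scenario_spec()].
#' @param out_dir Output directory.
#' @param quiet Suppress the log line.
#' @return The manifest tibble, invisibly.
#' @export
generate_synthetic <- function(scenario, out_dir, quiet = FALSE) {
  if (!inherits(scenario, "scenario_spec")) scenario <- read_scenario(scenario)
  manifest <- generate_cohort(scenario, out_dir)
  if (!quiet)
    message("synth: seed ", scenario$seed, ", ", nrow(manifest),
            " structure pairs (", scenario$n_periods, " periods x ",
            scenario$patients_per_period, " patients x ",
            length(scenario$oar_defs), " OARs) written to ", out_dir)
  invisible(manifest)
}

#' Read a scenario file
#'
#' @param path YAML file naming a `preset` plus optional overrides (see
#'   [generate_synthetic()]).
#' @return A [scenario_spec()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$preset))
    stop("scenario file must name a `preset`", call. = FALSE)
  args <- list(name = y$preset)
  for (k in c("seed", "n_periods", "patients_per_period", "update_period",
              "failure_period", "failure_prob"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  for (k in c("grid_shape", "spacing_mm"))
    if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
  do.call(scenario_preset, args)
}
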