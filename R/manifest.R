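#' Load a cohort manifest and resolve structure pairs
#'
#' The manifest lists one row per audited structure: patient id, acquisition
#' date, structure name as recorded clinically, and paths to the DLAS and
#' final approved masks. Rows are matched against the protocol (directly or
#' via aliases, after name normalization) and their mask files loaded and
#' checked for a shared grid. A row that fails any step goes to `unresolved`
#' with a reason code — `name-mismatch`, `bad-date`, `missing-file`,
#' `load-error` or `grid-mismatch` — and never aborts the load; unmatched
#' structures are an expected feature of script-based audits (structures
#' named off-protocol are missed, and the miss rate is itself reported).
#'
#' @param manifest_path CSV file with header
#'   `patient_id,date,oar_name,dlas_path,final_path`, or a JSON array of
#'   objects with the same fields. Relative mask paths are resolved against
#'   the manifest's directory.
#' @param config An [audit_config()].
#' @param load_masks If `FALSE`, only name/date/file-existence checks are
#'   performed and `pairs` is not populated (useful for quick validation).
#' @return An object of class `cohort_manifest`: list with
#'   \describe{
#'     \item{entries}{tibble of resolved rows with canonical `oar_name`}
#'     \item{pairs}{list of `structure_pair` objects parallel to `entries`}
#'     \item{unresolved}{tibble of failed rows with a `reason` column}
#'   }
#' @export
load_manifest <- function(manifest_path, config, load_masks = TRUE) {
  stopifnot(inherits(config, "audit_config"))
  raw <- read_manifest_table(manifest_path)
  base_dir <- dirname(normalizePath(manifest_path, mustWork = TRUE))

  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  canonical <- resolve_oar_name(raw$oar_name, config)
  reason[is.na(canonical)] <- "name-mismatch"

  dates <- rep(as.Date(NA), n)
  ok <- is.na(reason)
  parsed <- as.Date(as.character(raw$date[ok]), format = "%Y-%m-%d")
  dates[ok] <- parsed
  reason[ok][is.na(parsed)] <- "bad-date"

  resolve_path <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }
  dlas_paths <- resolve_path(raw$dlas_path)
  final_paths <- resolve_path(raw$final_path)

  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    if (!file.exists(dlas_paths[i]) || !file.exists(final_paths[i])) {
      reason[i] <- "missing-file"
      next
    }
    if (!load_masks) next
    dlas <- tryCatch(read_mask(dlas_paths[i]), error = function(e) NULL)
    fin <- tryCatch(read_mask(final_paths[i]), error = function(e) NULL)
    if (is.null(dlas) || is.null(fin)) {
      reason[i] <- "load-error"
      next
    }
    pair <- tryCatch(
      structure_pair(patient_id = raw$patient_id[i],
                     oar_name = canonical[i],
                     acquisition_date = dates[i],
                     dlas = dlas, final = fin),
      error = function(e) NULL)
    if (is.null(pair)) {
      reason[i] <- "grid-mismatch"
      next
    }
    pairs[[i]] <- pair
  }

  resolved <- is.na(reason)
  entries <- tibble::tibble(
    patient_id = as.character(raw$patient_id[resolved]),
    date = dates[resolved],
    oar_name = canonical[resolved],
    dlas_path = dlas_paths[resolved],
    final_path = final_paths[resolved]
  )
  unresolved <- tibble::tibble(
    patient_id = as.character(raw$patient_id[!resolved]),
    date = as.character(raw$date[!resolved]),
    oar_name = as.character(raw$oar_name[!resolved]),
    dlas_path = as.character(raw$dlas_path[!resolved]),
    final_path = as.character(raw$final_path[!resolved]),
    reason = reason[!resolved]
  )
  structure(list(entries = entries,
                 pairs = pairs[resolved],
                 unresolved = unresolved),
            class = "cohort_manifest")
}

read_manifest_table <- function(path) {
  if (!file.exists(path))
    stop("manifest file not found: ", path, call. = FALSE)
  cols <- c("patient_id", "date", "oar_name", "dlas_path", "final_path")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    raw <- tibble::as_tibble(raw)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  }
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0)
    stop("manifest lacks required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw[cols]
}

#' One DLAS / final-approved structure pair
#'
#' @param patient_id Opaque patient identifier.
#' @param oar_name Canonical protocol OAR name.
#' @param acquisition_date `Date`.
#' @param dlas,final [binary_volume()] masks on an identical grid: the raw
#'   auto-segmentation output and the contour approved for planning.
#' @return An object of class `structure_pair`.
#' @export
structure_pair <- function(patient_id, oar_name, acquisition_date, dlas, final) {
  check_same_grid(dlas, final)
  structure(list(patient_id = as.character(patient_id),
                 oar_name = as.character(oar_name),
                 acquisition_date = parse_iso_date(acquisition_date),
                 dlas = dlas, final = final),
            class = "structure_pair")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d resolved entries, %d unresolved (%.1f%% failure rate)\n",
              nrow(x$entries), nrow(x$unresolved), 100 * failure_rate(x)))
  if (nrow(x$unresolved) > 0) {
    tab <- table(x$unresolved$reason)
    cat("  unresolved by reason:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Manifest failure rate
#'
#' Fraction of manifest rows that could not be resolved to an evaluable
#' structure pair — the audit's analogue of the case-matching failures a
#' script audit records against the treatment planning system.
#'
#' @param manifest A `cohort_manifest`.
#' @return Fraction in \[0, 1\].
#' @export
failure_rate <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  n <- nrow(manifest$entries) + nrow(manifest$unresolved)
  if (n == 0) return(0)
  nrow(manifest$unresolved) / n
}
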