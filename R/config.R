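#' Audit protocol configuration
#'
#' Describes the audit protocol: which OAR (organ-at-risk) names are
#' clinically relevant (only structures with a dose constraint in the local
#' protocol are audited), the surface-Dice tolerance per OAR, the calendar
#' period length, the audit start date, and the outlier rule parameters.
#'
#' @param oars Either a character vector of protocol OAR names (all given the
#'   default tolerance and no aliases), or a named list mapping each OAR name
#'   to a list with optional fields `tolerance_mm` and `aliases`.
#' @param audit_start Audit start date (ISO-8601 string or `Date`); period 0
#'   begins here.
#' @param period_length_months Length of one audit period in calendar months.
#' @param default_tolerance_mm Tolerance in mm used for OARs without their
#'   own override. 3 mm is the conventional choice, though it may not suit
#'   every OAR, hence the per-OAR override.
#' @param outlier_k Number of standard deviations below the OAR mean sDSC at
#'   which a case is flagged as an outlier.
#' @param min_n_for_outlier Minimum number of results an OAR needs before
#'   outlier flagging is attempted.
#' @return An object of class `audit_config`.
#' @examples
#' cfg <- audit_config(
#'   oars = list(
#'     Bladder      = list(),
#'     "Femoral Head" = list(aliases = c("FemHead_L", "Fem Head")),
#'     SpinalCord   = list(tolerance_mm = 2)
#'   ),
#'   audit_start = "2023-01-01"
#' )
#' @export
audit_config <- function(oars, audit_start,
                         period_length_months = 2L,
                         default_tolerance_mm = 3,
                         outlier_k = 2,
                         min_n_for_outlier = 5L) {
  if (is.character(oars)) {
    oars <- stats::setNames(rep(list(list()), length(oars)), oars)
  }
  if (!is.list(oars) || length(oars) == 0L || is.null(names(oars)) ||
      any(names(oars) == ""))
    stop("`oars` must be a non-empty named list or character vector", call. = FALSE)
  if (!is.numeric(default_tolerance_mm) || default_tolerance_mm <= 0)
    stop("`default_tolerance_mm` must be > 0", call. = FALSE)
  period_length_months <- as.integer(period_length_months)
  if (is.na(period_length_months) || period_length_months < 1L)
    stop("`period_length_months` must be a positive integer", call. = FALSE)
  if (!is.numeric(outlier_k) || outlier_k <= 0)
    stop("`outlier_k` must be > 0", call. = FALSE)
  min_n_for_outlier <- as.integer(min_n_for_outlier)
  if (is.na(min_n_for_outlier) || min_n_for_outlier < 1L)
    stop("`min_n_for_outlier` must be a positive integer", call. = FALSE)

  protocol <- lapply(names(oars), function(nm) {
    o <- oars[[nm]]
    tol <- if (!is.null(o$tolerance_mm)) as.numeric(o$tolerance_mm) else default_tolerance_mm
    if (!is.finite(tol) || tol <= 0)
      stop("tolerance for OAR '", nm, "' must be > 0", call. = FALSE)
    aliases <- unique(as.character(o$aliases %||% character()))
    list(name = nm, tolerance_mm = tol, aliases = aliases)
  })
  names(protocol) <- names(oars)

  # alias table keyed on normalised names; canonical names included
  keys <- unlist(lapply(unname(protocol), function(p)
    stats::setNames(rep(p$name, 1 + length(p$aliases)),
                    normalize_structure_name(c(p$name, p$aliases)))))
  # an alias normalizing to its own canonical name is redundant, not a clash
  keys <- keys[!duplicated(paste(names(keys), keys))]
  if (anyDuplicated(names(keys)))
    stop("OAR names/aliases collide after normalization: ",
         paste(unique(names(keys)[duplicated(names(keys))]), collapse = ", "),
         call. = FALSE)

  structure(list(
    protocol_oars = protocol,
    alias_lookup = keys,
    audit_start = parse_iso_date(audit_start, "audit_start"),
    period_length_months = period_length_months,
    default_tolerance_mm = default_tolerance_mm,
    outlier_k = as.numeric(outlier_k),
    min_n_for_outlier = min_n_for_outlier
  ), class = "audit_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 only; locale-dependent formats are deliberately rejected
parse_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d))
    stop(what, " must be an ISO-8601 date (YYYY-MM-DD), got: ",
         paste(x[is.na(d)], collapse = ", "), call. = FALSE)
  d
}

#' Normalize a structure name for protocol matching
#'
#' Case-folds and strips whitespace and underscores, so "Fem Head_L" and
#' "femhead l" collide deliberately. Names that still differ after this are
#' treated as distinct; unmatched structures are recorded, not guessed,
#' mirroring how script audits miss structures with non-standard names.
#'
#' @param x Character vector of structure names.
#' @return Normalized character vector.
#' @export
normalize_structure_name <- function(x) {
  tolower(gsub("[[:space:]_]+", "", as.character(x)))
}

#' Resolve a structure name against the protocol
#'
#' @param name Structure name as found in the data.
#' @param config An [audit_config()].
#' @return The canonical protocol OAR name, or `NA_character_` if the name
#'   does not match any protocol OAR or alias.
#' @export
resolve_oar_name <- function(name, config) {
  stopifnot(inherits(config, "audit_config"))
  key <- normalize_structure_name(name)
  out <- unname(config$alias_lookup[key])
  out[is.na(key) | !(key %in% names(config$alias_lookup))] <- NA_character_
  out
}

#' Tolerance for an OAR
#' @inheritParams resolve_oar_name
#' @param oar_name Canonical protocol OAR name.
#' @return Tolerance in mm.
#' @export
oar_tolerance <- function(oar_name, config) {
  stopifnot(inherits(config, "audit_config"))
  p <- config$protocol_oars[[oar_name]]
  if (is.null(p)) stop("'", oar_name, "' is not a protocol OAR", call. = FALSE)
  p$tolerance_mm
}

#' Read an audit configuration from a YAML file
#'
#' Expected keys: `audit_start`, and optionally `period_length_months`,
#' `default_tolerance_mm`, `outlier_k`, `min_n_for_outlier`, and `oars` —
#' either a list of names or a map of name to `{tolerance_mm, aliases}`.
#'
#' @param path Path to a YAML config file.
#' @return An [audit_config()].
#' @examples
#' cfg <- read_audit_config(
#'   system.file("extdata", "example_config.yaml", package = "oaraudit"))
#' cfg
#' @export
read_audit_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$oars) || is.null(y$audit_start))
    stop("config must define `oars` and `audit_start`", call. = FALSE)
  oars <- y$oars
  if (is.character(oars) ||
      (is.list(oars) && is.null(names(oars)))) {
    oars <- as.character(unlist(oars))
  }
  audit_config(
    oars = oars,
    audit_start = y$audit_start,
    period_length_months = y$period_length_months %||% 2L,
    default_tolerance_mm = y$default_tolerance_mm %||% 3,
    outlier_k = y$outlier_k %||% 2,
    min_n_for_outlier = y$min_n_for_outlier %||% 5L
  )
}

#' @export
print.audit_config <- function(x, ...) {
  cat(sprintf(paste0("<audit_config> %d protocol OARs, start %s, ",
                     "%d-month periods, default tolerance %g mm, outlier k = %g\n"),
              length(x$protocol_oars), format(x$audit_start),
              x$period_length_months, x$default_tolerance_mm, x$outlier_k))
  invisible(x)
}
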