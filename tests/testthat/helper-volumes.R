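# fixture builders used across test files

make_cube <- function(dims = c(12L, 12L, 12L), from = 3L, size = 6L,
                      spacing = c(1, 1, 1), shift = c(0L, 0L, 0L)) {
  g <- array(FALSE, dims)
  lo <- from + shift
  hi <- from + size - 1L + shift
  g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_volume(g, spacing_mm = spacing)
}

single_voxel <- function(dims, at, spacing = c(1, 1, 1)) {
  g <- array(FALSE, dims)
  g[at[1], at[2], at[3]] <- TRUE
  binary_volume(g, spacing_mm = spacing)
}

empty_volume <- function(dims = c(6L, 6L, 6L), spacing = c(1, 1, 1)) {
  binary_volume(array(FALSE, dims), spacing_mm = spacing)
}

# tiny protocol used throughout the audit tests
tiny_config <- function(...) {
  audit_config(
    oars = list(
      Bladder = list(),
      "Femoral Head" = list(aliases = c("Fem Head L", "FemHead")),
      SpinalCord = list(tolerance_mm = 2)
    ),
    audit_start = "2023-01-01",
    ...
  )
}

# a results tibble without running geometry, for aggregation tests
make_results <- function(oar, sdsc, unedited = rep(FALSE, length(sdsc)),
                         period = rep(0L, length(sdsc)),
                         patient = sprintf("P%02d", seq_along(sdsc))) {
  tibble::tibble(
    patient_id = patient,
    oar_name = rep_len(oar, length(sdsc)),
    date = as.Date("2023-01-15"),
    period_index = period,
    sdsc = sdsc,
    unedited = unedited,
    tolerance_mm = 3
  )
}
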