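#' Shipped scenario presets
#'
#' Ready-made synthetic cohorts emulating the editing regimes a clinical
#' DLAS audit encounters:
#' \describe{
#'   \item{`steady_state`}{editing behaviour constant across periods: about
#'     40% of contours used unedited, the rest receiving small margin, crop
#'     or local-patch edits of fixed magnitude.}
#'   \item{`drift`}{editing decreases over the audit: the unedited fraction
#'     rises linearly from 21.5% to 40% and edit magnitudes shrink, so mean
#'     sDSC rises across periods — the signature of users settling into an
#'     accepted tool.}
#'   \item{`model_update`}{one OAR (an ellipsoid standing in for a heart
#'     structure under-contoured superiorly) needs a superior-extent
#'     correction in early periods; from `update_period` on the vendor model
#'     is fixed and the edit disappears — a step change in one OAR's trend.}
#'   \item{`partial_failure`}{a tube OAR (oesophagus-like) where, in one
#'     period only, the DLAS retains just the inferior section for roughly
#'     half the patients — a localized failure the outlier flagging should
#'     surface.}
#'   \item{`parameter_recovery`}{a single-OAR, single-period cohort with
#'     `p_unedited = 0.6`, used to check that the audited unedited
#'     percentage recovers the generating probability.}
#' }
#'
#' All presets use three base OARs (a bladder-like ellipsoid and two tube
#' organs emulating spinal cord and oesophagus) on a 48^3 grid at
#' 1 x 1 x 2.5 mm spacing unless reduced via `grid_shape`/`spacing_mm`,
#' which rescales the anatomy proportionally.
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param n_periods Number of periods (default 9, an 18-month audit at
#'   2-month periods).
#' @param patients_per_period Patients per period.
#' @param grid_shape,spacing_mm Grid geometry for all shapes.
#' @param update_period For `model_update`: first period with the fixed
#'   model.
#' @param failure_period,failure_prob For `partial_failure`: affected period
#'   and per-case probability of the failure.
#' @return A [scenario_spec()].
#' @export
scenario_preset <- function(name = c("steady_state", "drift", "model_update",
                                     "partial_failure", "parameter_recovery"),
                            seed = 1L, n_periods = 9L,
                            patients_per_period = 20L,
                            grid_shape = c(48L, 48L, 48L),
                            spacing_mm = c(1, 1, 2.5),
                            update_period = 3L,
                            failure_period = 5L, failure_prob = 5 / 11) {
  name <- match.arg(name)
  shapes <- preset_shapes(grid_shape, spacing_mm)

  # characteristic edit mixtures; magnitude m in mm scales all components.
  # Patch depth m + 2 straddles the 3 mm tolerance: early heavy edits are
  # visible to the surface Dice, late sub-tolerance edits are not — the same
  # asymmetry a clinical audit at a fixed tolerance exhibits.
  parallel_edits <- function(m) list(
    list(prob = 0.4, edit = edit_margin(m)),
    list(prob = 0.2, edit = edit_margin(-m)),
    list(prob = 0.4, edit = edit_bump(2, radius_mm = 4, depth_mm = min(m + 2, 4)))
  )
  serial_edits <- function(m, crop = 0.2) list(
    list(prob = 0.5, edit = edit_margin(m)),
    list(prob = 0.3, edit = edit_crop(crop)),
    list(prob = 0.2, edit = edit_bump(1, radius_mm = 4, depth_mm = min(m + 2, 4)))
  )

  defs <- switch(name,
    steady_state = {
      lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
        ed <- if (shapes[[nm]]$kind == "ellipsoid") parallel_edits(1) else serial_edits(1)
        list(shape = shapes[[nm]],
             periods = edit_distribution(0.40, ed))
      })
    },
    drift = {
      # unedited fraction 21.5% -> 40%, edit magnitude 2 mm -> 0.5 mm
      p_seq <- seq(0.215, 0.40, length.out = n_periods)
      m_seq <- seq(2, 0.5, length.out = n_periods)
      c_seq <- seq(0.3, 0.1, length.out = n_periods)
      lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
        per <- lapply(seq_len(n_periods), function(p) {
          ed <- if (shapes[[nm]]$kind == "ellipsoid") parallel_edits(m_seq[p])
                else serial_edits(m_seq[p], c_seq[p])
          edit_distribution(p_seq[p], ed)
        })
        list(shape = shapes[[nm]], periods = per)
      })
    },
    model_update = {
      defs <- lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
        ed <- if (shapes[[nm]]$kind == "ellipsoid") parallel_edits(1) else serial_edits(1)
        list(shape = shapes[[nm]], periods = edit_distribution(0.40, ed))
      })
      # extra OAR whose superior aspect is under-contoured until the update
      heart <- shapes$bladder
      pre <- edit_distribution(0.05, list(
        list(prob = 1, edit = edit_crop(0.3, side = "superior"))))
      post <- edit_distribution(0.60, parallel_edits(0.5))
      per <- lapply(seq_len(n_periods), function(p)
        if (p - 1 < update_period) pre else post)
      defs$heart_apulm <- list(shape = heart, periods = per)
      defs
    },
    partial_failure = {
      lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
        base <- if (shapes[[nm]]$kind == "ellipsoid")
          edit_distribution(0.40, parallel_edits(1))
        else edit_distribution(0.40, serial_edits(1))
        if (nm != "oesophagus")
          return(list(shape = shapes[[nm]], periods = base))
        # in the failure period only: inferior section retained for ~half
        # the cases (a large superior crop), tiny edits otherwise
        fail <- edit_distribution(0, list(
          list(prob = failure_prob, edit = edit_crop(0.6, side = "superior")),
          list(prob = 1 - failure_prob, edit = edit_margin(0.5))))
        per <- lapply(seq_len(n_periods), function(p)
          if (p - 1 == failure_period) fail else base)
        list(shape = shapes[[nm]], periods = per)
      })
    },
    parameter_recovery = {
      list(bladder = list(
        shape = shapes$bladder,
        periods = edit_distribution(0.6, parallel_edits(1))))
    }
  )
  if (name == "parameter_recovery") n_periods <- 1L
  scenario_spec(defs, n_periods = n_periods,
                patients_per_period = patients_per_period, seed = seed)
}

# base anatomy scaled to the grid's physical extent; at the default
# 48^3 x (1,1,2.5) mm grid the bladder ellipsoid is ~15 x 13 x 20 mm and the
# tubes ~4-5 mm radius, 65-76 mm long
preset_shapes <- function(grid_shape = c(48L, 48L, 48L),
                          spacing_mm = c(1, 1, 2.5)) {
  ext <- (as.integer(grid_shape) - 1) * as.numeric(spacing_mm)
  ctr <- ext / 2
  list(
    bladder = shape_spec("ellipsoid", ctr,
                         radii_mm = c(0.32 * ext[1], 0.28 * ext[2], 0.17 * ext[3]),
                         grid_shape = grid_shape, spacing_mm = spacing_mm),
    spinal_cord = shape_spec("tube", ctr, radius_mm = 0.10 * ext[1],
                             length_mm = 0.65 * ext[3],
                             grid_shape = grid_shape, spacing_mm = spacing_mm),
    oesophagus = shape_spec("tube", ctr, radius_mm = 0.085 * ext[1],
                            length_mm = 0.55 * ext[3],
                            grid_shape = grid_shape, spacing_mm = spacing_mm)
  )
}

#' Audit configuration matching the synthetic presets
#'
#' Convenience: an [audit_config()] whose protocol lists the preset OAR
#' names with the default 3 mm tolerance, anchored at the scenario's start
#' date and period length.
#'
#' @param scenario A [scenario_spec()].
#' @param ... Passed on to [audit_config()] (e.g. `outlier_k`).
#' @return An [audit_config()].
#' @export
preset_audit_config <- function(scenario, ...) {
  stopifnot(inherits(scenario, "scenario_spec"))
  audit_config(oars = names(scenario$oar_defs),
               audit_start = scenario$audit_start,
               period_length_months = scenario$period_length_months,
               ...)
}
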