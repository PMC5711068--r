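#' MLC segment: one static aperture with a monitor-unit weight
#'
#' A segment is a single static multileaf-collimator aperture: one coordinate
#' per leaf for the left bank and one for the right bank, both in cm projected
#' to the isocenter plane, plus the monitor units (MU) delivered while the
#' aperture is held. Coordinates are bank-signed so that the per-leaf opening
#' is `left - right >= 0`.
#'
#' @param left_positions Numeric vector, left-bank leaf coordinates (cm).
#' @param right_positions Numeric vector, same length, right-bank coordinates.
#' @param mu_weight Monitor units for this segment (finite, `>= 0`).
#' @return An object of class `mlc_segment`.
#' @export
mlc_segment <- function(left_positions, right_positions, mu_weight) {
  check_finite(left_positions, "left_positions")
  check_finite(right_positions, "right_positions")
  if (length(left_positions) != length(right_positions) ||
      length(left_positions) < 1L)
    stop_imrtqa("left_positions and right_positions must have equal length >= 1")
  if (any(left_positions < right_positions))
    stop_imrtqa("aperture must satisfy left >= right for every leaf pair")
  check_finite(mu_weight, "mu_weight")
  if (length(mu_weight) != 1L || mu_weight < 0)
    stop_imrtqa("mu_weight must be a single value >= 0")
  structure(
    list(left_positions = as.numeric(left_positions),
         right_positions = as.numeric(right_positions),
         mu_weight = as.numeric(mu_weight)),
    class = "mlc_segment")
}

#' Treatment beam: gantry angle plus an ordered list of MLC segments
#'
#' @param gantry_deg Gantry angle in degrees, normalized to `[0, 360)`.
#' @param segments List of [mlc_segment()] objects sharing one leaf count.
#' @param beam_mu Total beam MU; defaults to the sum of segment weights and
#'   must agree with it to within 1e-9 relative when given.
#' @return An object of class `rt_beam`.
#' @export
rt_beam <- function(gantry_deg, segments, beam_mu = NULL) {
  check_finite(gantry_deg, "gantry_deg")
  gantry_deg <- as.numeric(gantry_deg) %% 360
  if (!is.list(segments) || length(segments) < 1L ||
      !all(vapply(segments, inherits, logical(1), "mlc_segment")))
    stop_imrtqa("segments must be a non-empty list of mlc_segment objects")
  nleaf <- vapply(segments, function(s) length(s$left_positions), integer(1))
  if (length(unique(nleaf)) != 1L)
    stop_imrtqa("all segments in a beam must share the same leaf count")
  mu_sum <- sum(vapply(segments, `[[`, numeric(1), "mu_weight"))
  if (is.null(beam_mu)) beam_mu <- mu_sum
  if (beam_mu <= 0) stop_imrtqa("beam_mu must be > 0")
  if (!rel_equal(beam_mu, mu_sum))
    stop_imrtqa("beam_mu must equal the sum of segment mu_weights")
  structure(
    list(gantry_deg = gantry_deg, segments = segments,
         beam_mu = as.numeric(beam_mu)),
    class = "rt_beam")
}

#' IMRT plan: a set of beams with total monitor units
#'
#' @param plan_id Character identifier.
#' @param beams Non-empty list of [rt_beam()] objects.
#' @param plan_mu Total plan MU; defaults to and must match the beam sum.
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(plan_id, beams, plan_mu = NULL) {
  if (!is.character(plan_id) || length(plan_id) != 1L)
    stop_imrtqa("plan_id must be a single string")
  if (!is.list(beams) || length(beams) < 1L ||
      !all(vapply(beams, inherits, logical(1), "rt_beam")))
    stop_imrtqa("beams must be a non-empty list of rt_beam objects")
  mu_sum <- sum(vapply(beams, `[[`, numeric(1), "beam_mu"))
  if (is.null(plan_mu)) plan_mu <- mu_sum
  if (!rel_equal(plan_mu, mu_sum))
    stop_imrtqa("plan_mu must equal the sum of beam_mu values")
  structure(
    list(plan_id = plan_id, beams = beams, plan_mu = as.numeric(plan_mu)),
    class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  nseg <- vapply(x$beams, function(b) length(b$segments), integer(1))
  ang <- vapply(x$beams, `[[`, numeric(1), "gantry_deg")
  cat("IMRT plan '", x$plan_id, "': ", length(x$beams), " beams, ",
      sum(nseg), " segments, ", format(x$plan_mu), " MU\n", sep = "")
  cat("  gantry angles (deg):", paste(format(ang, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Collapse a plan onto a single gantry angle
#'
#' The single-gantry-angle composite (SGAC, "collapsed") QA technique delivers
#' every beam of a plan from one gantry angle instead of the planned angles.
#' The transform changes only `gantry_deg`; every leaf position and MU weight
#' is carried through untouched, so all MU totals and complexity scores are
#' preserved exactly.
#'
#' @param plan An [rt_plan()].
#' @param target_angle Gantry angle (degrees) given to every beam; default 0.
#' @return A new `rt_plan` with all beams at `target_angle`.
#' @export
collapse_plan <- function(plan, target_angle = 0) {
  stopifnot(inherits(plan, "rt_plan"))
  check_finite(target_angle, "target_angle")
  plan$beams <- lapply(plan$beams, function(b) {
    b$gantry_deg <- as.numeric(target_angle) %% 360
    b
  })
  plan
}

n_leaf_pairs <- function(beam) length(beam$segments[[1L]]$left_positions)
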