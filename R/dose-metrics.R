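#' Exact cumulative dose-volume histogram over a structure
#'
#' Voxel-rank cumulative DVH without binning loss: the dose edges are the
#' sorted unique voxel doses inside the mask and the curve value at each edge
#' is the fraction of structure voxels receiving at least that dose.
#'
#' @param grid A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on the same lattice.
#' @return An object of class `dvh` with fields `dose_edges` (Gy, ascending)
#'   and `cum_volume_fraction` (non-increasing, starts at 1).
#' @export
cumulative_dvh <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!same_lattice(grid, mask))
    stop_imrtqa("mask and grid are on different lattices")
  d <- grid$values[mask$voxels]
  if (length(d) == 0L) stop_imrtqa("empty structure mask")
  sorted <- sort(d)                 # ascending
  n <- length(sorted)
  runs <- rle(sorted)
  edges <- runs$values
  # voxels with dose >= edge: n minus the count strictly below the edge
  below <- cumsum(c(0, runs$lengths[-length(runs$lengths)]))
  frac <- (n - below) / n
  structure(list(dose_edges = edges, cum_volume_fraction = frac,
                 n_voxels = n, doses = sorted),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat("cumulative DVH over", x$n_voxels, "voxels; dose range [Gy]:",
      format(min(x$dose_edges), digits = 4), "-",
      format(max(x$dose_edges), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.dvh <- function(x, ...) {
  graphics::plot(x$dose_edges, 100 * x$cum_volume_fraction, type = "s",
                 xlab = "Dose [Gy]", ylab = "Volume [%]",
                 main = "Cumulative DVH", ...)
  invisible(x)
}

#' Dose covering a given fraction of the structure volume
#'
#' `D_x%` on the voxel-rank convention: the largest dose received by at
#' least `x%` of the structure volume, i.e. the `ceil(x/100 * n)`-th voxel
#' dose in descending order, with no interpolation. `D100%` is the minimum
#' voxel dose.
#'
#' @param dvh A [cumulative_dvh()] result.
#' @param volume_pct Volume percentage in `(0, 100]`.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_pct) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.numeric(volume_pct) || volume_pct <= 0 || volume_pct > 100)
    stop_imrtqa("volume_pct must be in (0, 100]")
  n <- dvh$n_voxels
  k <- ceiling(volume_pct / 100 * n)
  sort(dvh$doses, decreasing = TRUE)[k]
}

#' Homogeneity index of the dose within a structure
#'
#' `HI = (D2% - D98%) / D_average` over the structure (typically the chamber
#' contour). 0 means perfectly uniform dose; larger values mean a more
#' heterogeneous dose, which for point-dose QA signals a measurement more
#' sensitive to chamber positioning and volume averaging.
#'
#' @param grid A [dose_grid()].
#' @param chamber_mask A [structure_mask()] with mean dose `> 0`.
#' @return HI, unitless `>= 0`.
#' @export
homogeneity_index <- function(grid, chamber_mask) {
  dvh <- cumulative_dvh(grid, chamber_mask)
  davg <- mean(dvh$doses)
  if (davg <= 0) stop_imrtqa("average structure dose is zero")
  (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / davg
}

#' Conformity index of the reference isodose around the chamber
#'
#' With reference isodose RI equal to the mean chamber dose, forms
#' `COIN = (V_chamber>=RI / V_chamber) * (V_chamber>=RI / V_shell>=RI)`,
#' where the shell is the chamber expanded by a margin (1.5 cm in this QA
#' protocol) and includes the chamber. A value near 1 means the reference
#' isodose hugs the chamber tightly — a steep gradient making the
#' measurement sensitive to positioning; lower values mean the isodose also
#' covers the surroundings, so positioning is less critical.
#'
#' @param grid A [dose_grid()].
#' @param chamber_mask Non-empty chamber [structure_mask()].
#' @param shell_mask [structure_mask()] containing the chamber (see
#'   [expand_mask()]).
#' @return COIN in `[0, 1]`.
#' @export
conformity_index <- function(grid, chamber_mask, shell_mask) {
  stopifnot(inherits(grid, "dose_grid"),
            inherits(chamber_mask, "structure_mask"),
            inherits(shell_mask, "structure_mask"))
  if (!same_lattice(grid, chamber_mask) || !same_lattice(grid, shell_mask))
    stop_imrtqa("masks and grid are on different lattices")
  if (!any(chamber_mask$voxels)) stop_imrtqa("empty chamber mask")
  if (any(chamber_mask$voxels & !shell_mask$voxels))
    stop_imrtqa("shell_mask must contain chamber_mask")
  ri <- mean(grid$values[chamber_mask$voxels])
  v_ch <- sum(chamber_mask$voxels)
  v_ch_ri <- sum(grid$values[chamber_mask$voxels] >= ri)
  v_shell_ri <- sum(grid$values[shell_mask$voxels] >= ri)
  if (v_shell_ri == 0)
    stop_imrtqa("reference isodose covers no shell voxel; COIN undefined")
  (v_ch_ri / v_ch) * (v_ch_ri / v_shell_ri)
}

#' Does a beam's dose distribution intersect the chamber?
#'
#' A quantitative surrogate for visual inspection: a beam intersects the
#' chamber when any chamber voxel receives at least `frac_of_max` of the
#' beam's maximum dose anywhere in the grid. The default threshold of 0.25
#' is set below the ratio a beam passing straight through the chamber
#' attains after attenuation over the longest phantom path (about 0.35 for
#' a 30 cm water path at 6 MV), while beams whose aperture misses the
#' chamber leave only penumbra tails well under it; a 0.5 threshold would
#' misclassify lateral through-beams as misses purely because of depth
#' attenuation.
#'
#' @param beam_dose Per-beam [dose_grid()].
#' @param chamber_mask Chamber [structure_mask()].
#' @param frac_of_max Threshold fraction in `(0, 1)`.
#' @return `TRUE`/`FALSE`; an all-zero beam dose gives `FALSE`.
#' @export
beam_intersects_chamber <- function(beam_dose, chamber_mask,
                                    frac_of_max = 0.25) {
  stopifnot(inherits(beam_dose, "dose_grid"),
            inherits(chamber_mask, "structure_mask"))
  if (frac_of_max <= 0 || frac_of_max >= 1)
    stop_imrtqa("frac_of_max must be in (0, 1)")
  mx <- max(beam_dose$values)
  if (mx == 0) return(FALSE)
  any(beam_dose$values[chamber_mask$voxels] >= frac_of_max * mx)
}

#' Fraction of a plan's beams intersecting the chamber
#'
#' @param beam_doses Non-empty list of per-beam [dose_grid()]s.
#' @param chamber_mask Chamber [structure_mask()].
#' @param frac_of_max Threshold passed to [beam_intersects_chamber()].
#' @return Fraction in `[0, 1]`.
#' @export
intersection_fraction <- function(beam_doses, chamber_mask,
                                  frac_of_max = 0.25) {
  if (!is.list(beam_doses) || length(beam_doses) < 1L)
    stop_imrtqa("beam_doses must be a non-empty list")
  hits <- vapply(beam_doses, beam_intersects_chamber, logical(1),
                 chamber_mask = chamber_mask, frac_of_max = frac_of_max)
  mean(hits)
}

#' Combined per-beam statistical uncertainty of a plan dose
#'
#' Quadrature combination of the per-beam Type-A uncertainties of the dose
#' in the chamber: `sqrt(sum(i^2)) / n` for `n` beams. For equal per-beam
#' uncertainty `i` this reduces to `i / sqrt(n)`.
#'
#' @param per_beam_pct Numeric vector of per-beam uncertainties in percent.
#' @param n Number of beams; defaults to `length(per_beam_pct)` and must
#'   match it.
#' @return Combined uncertainty in percent.
#' @export
combined_uncertainty <- function(per_beam_pct, n = length(per_beam_pct)) {
  if (length(per_beam_pct) < 1L) stop_imrtqa("empty uncertainty list")
  check_finite(per_beam_pct, "per_beam_pct")
  if (any(per_beam_pct < 0)) stop_imrtqa("uncertainties must be >= 0")
  if (n != length(per_beam_pct))
    stop_imrtqa("n must equal the number of per-beam uncertainties")
  sqrt(sum(per_beam_pct^2)) / n
}

#' Percent relative root-mean-square difference
#'
#' RMS of the per-pair percent relative differences
#' `(computed - reference) / reference * 100`.
#'
#' @param computed,reference Numeric vectors of equal length; references
#'   must be `> 0`.
#' @return Percent RMS difference.
#' @export
percent_rms_difference <- function(computed, reference) {
  check_finite(computed, "computed"); check_finite(reference, "reference")
  if (length(computed) != length(reference) || length(computed) < 1L)
    stop_imrtqa("computed and reference must be equal-length, non-empty")
  if (any(reference <= 0)) stop_imrtqa("reference values must be > 0")
  sqrt(mean(((computed - reference) / reference * 100)^2))
}
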