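#' Modulation complexity scoring for MLC plans
#'
#' The modulation complexity score (MCS) quantifies how far a step-and-shoot
#' MLC delivery departs from a single static rectangular field. Per segment
#' it combines two unitless factors in `[0, 1]`:
#'
#' * **LSV** (leaf sequence variability): within each bank, how variable the
#'   positions of adjacent open leaves are relative to the bank's positional
#'   range (`posmax`). Aligned leaves give 1; large adjacent jumps drive the
#'   score down.
#' * **AAV** (aperture area variability): the segment's total opening
#'   relative to the maximal per-leaf opening reached anywhere in the same
#'   beam. The largest aperture of the beam scores 1.
#'
#' Segment scores are combined MU-weighted into a beam score, and beam scores
#' MU-weighted into a plan score, so an unmodulated static rectangular plan
#' scores exactly 1 and more heavily modulated plans score lower. No gantry,
#' collimator or couch angle enters the computation, so the score is
#' invariant under the collapsed-delivery transform.
#'
#' A leaf pair counts as *open* when its gap `left - right` exceeds
#' `gap_threshold` (cm); this keeps pairs parked closed behind the jaws from
#' dominating the LSV.
#'
#' @param plan An [rt_plan()].
#' @param beam An [rt_beam()].
#' @param gap_threshold Minimum gap (cm) for a leaf pair to count as open.
#' @return `plan_mcs()` and `beam_mcs()` return a single score in `[0, 1]`.
#'   `plan_complexity()` returns a `complexity_scores` object holding the
#'   per-segment LSV/AAV, per-beam MCS, and the plan MCS.
#' @export
plan_mcs <- function(plan, gap_threshold = 0.05) {
  stopifnot(inherits(plan, "rt_plan"))
  mcs_b <- vapply(plan$beams, beam_mcs, numeric(1),
                  gap_threshold = gap_threshold)
  mu_b <- vapply(plan$beams, `[[`, numeric(1), "beam_mu")
  sum(mcs_b * mu_b) / plan$plan_mu
}

#' @rdname plan_mcs
#' @export
beam_mcs <- function(beam, gap_threshold = 0.05) {
  stopifnot(inherits(beam, "rt_beam"))
  bm <- beam_max_aperture(beam)
  scores <- vapply(seq_along(beam$segments), function(i) {
    s <- beam$segments[[i]]
    open <- open_leaves(s, gap_threshold)
    if (!any(open)) return(0)   # closed aperture: zero area, nothing varies
    aav <- tryCatch(
      segment_aav(s, bm$left, bm$right),
      error = function(e) stop_imrtqa("segment ", i, ": ", conditionMessage(e)))
    lsv <- tryCatch(
      segment_lsv(s, open),
      error = function(e) stop_imrtqa("segment ", i, ": ", conditionMessage(e)))
    aav * lsv
  }, numeric(1))
  mu <- vapply(beam$segments, `[[`, numeric(1), "mu_weight")
  sum(scores * mu) / beam$beam_mu
}

# Per-leaf maximal opening coordinates over all segments of a beam: the
# largest left-bank and smallest right-bank coordinate each leaf reaches.
beam_max_aperture <- function(beam) {
  lefts <- vapply(beam$segments, `[[`, numeric(n_leaf_pairs(beam)),
                  "left_positions")
  rights <- vapply(beam$segments, `[[`, numeric(n_leaf_pairs(beam)),
                   "right_positions")
  lefts <- matrix(lefts, nrow = n_leaf_pairs(beam))
  rights <- matrix(rights, nrow = n_leaf_pairs(beam))
  list(left = apply(lefts, 1L, max), right = apply(rights, 1L, min))
}

#' @rdname plan_mcs
#' @param segment An [mlc_segment()].
#' @export
open_leaves <- function(segment, gap_threshold = 0.05) {
  segment$left_positions - segment$right_positions > gap_threshold
}

#' Positional range of the open leaves of one bank
#'
#' `posmax` is the spread `max(pos) - min(pos)` of the leaf coordinates of
#' one bank, taken over the open leaves of a segment. It normalizes the
#' adjacent-leaf differences inside the LSV.
#'
#' @param bank_positions Leaf coordinates (cm) for one bank.
#' @param open_mask Logical vector marking the open leaf pairs.
#' @return Non-negative length in cm.
#' @export
segment_posmax <- function(bank_positions, open_mask) {
  check_finite(bank_positions, "bank_positions")
  if (length(open_mask) != length(bank_positions))
    stop_imrtqa("open_mask length must match bank_positions")
  p <- bank_positions[open_mask]
  if (length(p) == 0L) stop_imrtqa("no open leaves in segment")
  max(p) - min(p)
}

#' Leaf sequence variability of one segment
#'
#' Per bank, sums `posmax - |pos_n - pos_(n+1)|` over the N-1 adjacent pairs
#' of the N open leaves and normalizes by `(N-1) * posmax`; the two bank
#' factors multiply. A bank with a single open leaf or with all open leaves
#' aligned (`posmax = 0`) is perfectly regular and contributes factor 1.
#'
#' @param segment An [mlc_segment()].
#' @param open_mask Logical vector from [open_leaves()].
#' @return LSV in `[0, 1]`.
#' @export
segment_lsv <- function(segment, open_mask) {
  stopifnot(inherits(segment, "mlc_segment"))
  bank_factor <- function(pos) {
    p <- pos[open_mask]
    if (length(p) == 0L) stop_imrtqa("no open leaves in segment")
    n <- length(p)
    pm <- max(p) - min(p)
    if (n == 1L || pm == 0) return(1)
    d <- abs(diff(p))
    sum(pm - d) / ((n - 1) * pm)
  }
  bank_factor(segment$left_positions) * bank_factor(segment$right_positions)
}

#' Aperture area variability of one segment
#'
#' Ratio of the segment's summed per-leaf opening to the summed maximal
#' per-leaf opening reached over all segments of the same beam (leaf widths
#' are uniform, so openings stand in for areas).
#'
#' @param segment An [mlc_segment()].
#' @param beam_max_left,beam_max_right Per-leaf maximal opening coordinates
#'   of the beam, as produced by `beam_max_aperture()`.
#' @return AAV in `[0, 1]`.
#' @export
segment_aav <- function(segment, beam_max_left, beam_max_right) {
  stopifnot(inherits(segment, "mlc_segment"))
  denom <- sum(beam_max_left - beam_max_right)
  if (denom <= 0)
    stop_imrtqa("beam never opens: zero maximal aperture area")
  sum(segment$left_positions - segment$right_positions) / denom
}

#' @rdname plan_mcs
#' @export
plan_complexity <- function(plan, gap_threshold = 0.05) {
  stopifnot(inherits(plan, "rt_plan"))
  per_beam <- lapply(seq_along(plan$beams), function(j) {
    beam <- plan$beams[[j]]
    bm <- beam_max_aperture(beam)
    lsv <- vapply(beam$segments, function(s) {
      open <- open_leaves(s, gap_threshold)
      if (!any(open)) NA_real_ else segment_lsv(s, open)
    }, numeric(1))
    aav <- vapply(beam$segments, function(s)
      segment_aav(s, bm$left, bm$right), numeric(1))
    mu <- vapply(beam$segments, `[[`, numeric(1), "mu_weight")
    data.frame(beam = j, segment = seq_along(beam$segments),
               lsv = lsv, aav = aav, mu_weight = mu)
  })
  seg_tab <- do.call(rbind, per_beam)
  mcs_b <- vapply(plan$beams, beam_mcs, numeric(1),
                  gap_threshold = gap_threshold)
  mu_b <- vapply(plan$beams, `[[`, numeric(1), "beam_mu")
  structure(
    list(plan_id = plan$plan_id,
         segments = seg_tab,
         mcs_beam = mcs_b,
         mu_beam = mu_b,
         mcs_plan = sum(mcs_b * mu_b) / plan$plan_mu,
         gap_threshold = gap_threshold),
    class = "complexity_scores")
}

#' @export
print.complexity_scores <- function(x, ...) {
  cat("Plan complexity for '", x$plan_id, "'\n", sep = "")
  cat("  MCS (plan):", format(x$mcs_plan, digits = 4), "\n")
  cat("  MCS per beam:",
      paste(format(x$mcs_beam, digits = 3), collapse = ", "), "\n")
  cat("  segments:", nrow(x$segments),
      " | LSV range:", paste(format(range(x$segments$lsv, na.rm = TRUE), digits = 3),
                             collapse = " - "),
      " | AAV range:", paste(format(range(x$segments$aav), digits = 3),
                             collapse = " - "), "\n")
  invisible(x)
}
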