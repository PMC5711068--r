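#' Small-field output correction factor kQclin (Alfonso formalism)
#'
#' Conventional reference dosimetry calibrates an ionization chamber in a
#' 10x10 cm^2 field; small, irregular composite IMRT fields break charged-
#' particle equilibrium, so the chamber's dose-to-water-per-cavity-dose
#' ratio shifts relative to the reference field. The correction factor is
#' the double ratio
#'
#' `k = (Dw_clin / Dair_clin) / (Dw_ref / Dair_ref)`
#'
#' where `Dw_*` is the dose to a water sphere of volume equal to the
#' chamber's active air cavity at the measurement point and `Dair_*` the
#' dose to the air cavity itself, for the clinical field and the reference
#' field respectively. The factor is 1 when the clinical field reproduces
#' reference conditions, and is invariant under any common rescaling of the
#' four doses.
#'
#' When per-value relative uncertainties (percent) are supplied, the
#' uncertainty of `k` is their quadrature sum, assuming independence.
#'
#' @param dw_clin,dair_clin Water-sphere and air-cavity dose (Gy) in the
#'   clinical field; both `> 0`.
#' @param dw_ref,dair_ref Same pair for the 10x10 cm^2 reference field.
#' @param rel_uncertainty_pct Optional numeric vector (length 4, ordered as
#'   the dose arguments) of relative uncertainties in percent.
#' @return The unitless factor; when uncertainties are supplied, a numeric
#'   with attribute `rel_uncertainty_pct`.
#' @export
k_qclin <- function(dw_clin, dair_clin, dw_ref, dair_ref,
                    rel_uncertainty_pct = NULL) {
  doses <- c(dw_clin, dair_clin, dw_ref, dair_ref)
  check_finite(doses, "doses")
  if (length(doses) != 4L || any(doses <= 0))
    stop_imrtqa("all four doses must be single positive values")
  k <- (dw_clin / dair_clin) / (dw_ref / dair_ref)
  if (!is.null(rel_uncertainty_pct)) {
    check_finite(rel_uncertainty_pct, "rel_uncertainty_pct")
    if (length(rel_uncertainty_pct) != 4L || any(rel_uncertainty_pct < 0))
      stop_imrtqa("rel_uncertainty_pct must be 4 non-negative values")
    attr(k, "rel_uncertainty_pct") <- sqrt(sum(rel_uncertainty_pct^2))
  }
  k
}

#' Convert a corrected chamber reading to dose to water in a clinical field
#'
#' `D_w = M * N_Dw * k_QQ0 * k_Qclin`: the influence-corrected reading `M`
#' (nC), the absorbed-dose-to-water calibration coefficient `N_Dw` (Gy/nC)
#' from the standards laboratory, the beam-quality correction `k_QQ0`
#' between the calibration quality and the clinic's reference field, and
#' the small-field factor from [k_qclin()]. With `k_Qclin = 1` this is the
#' conventional reference-dosimetry product.
#'
#' @param m_corrected Charge reading corrected for influence quantities (nC).
#' @param nd_w Calibration coefficient (Gy/nC).
#' @param kq_q0 Beam-quality correction factor (unitless).
#' @param kq_clin Small-field correction factor (unitless), default 1.
#' @return Absorbed dose to water in Gy.
#' @export
dose_to_water_from_reading <- function(m_corrected, nd_w, kq_q0,
                                       kq_clin = 1) {
  vals <- c(m_corrected, nd_w, kq_q0, kq_clin)
  check_finite(vals, "inputs")
  if (any(vals <= 0)) stop_imrtqa("all inputs must be > 0")
  m_corrected * nd_w * kq_q0 * as.numeric(kq_clin)
}

#' Monte Carlo simulation efficiency
#'
#' `epsilon = 1 / (T * sigma^2)` for CPU time `T` in seconds and estimated
#' percentage uncertainty `sigma`; the figure of merit for comparing
#' variance-reduction settings (halving `sigma` at fixed `T` quadruples it).
#'
#' @param cpu_seconds CPU time `T` in seconds, `> 0`.
#' @param sigma_pct Percentage uncertainty of the scored dose, `> 0`.
#' @return Efficiency in `1/(s * %^2)`.
#' @export
mc_efficiency <- function(cpu_seconds, sigma_pct) {
  check_finite(c(cpu_seconds, sigma_pct), "inputs")
  if (cpu_seconds <= 0 || sigma_pct <= 0)
    stop_imrtqa("cpu_seconds and sigma_pct must be > 0")
  1 / (cpu_seconds * sigma_pct^2)
}
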