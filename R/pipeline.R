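#' Per-patient QA comparison of rotated and collapsed delivery
#'
#' Runs the full metric set on one QA case for both delivery modes:
#' plan complexity (MCS — identical for both modes by construction), the
#' homogeneity index over the chamber contour, conformity index against the
#' dilated shell, the fraction of beams whose dose distribution crosses the
#' chamber contour, the cavity mean dose,
#' the quadrature-combined per-beam Type-A uncertainty, the [k_qclin()]
#' surrogate factor (water-sphere vs chamber-cavity dose, clinical vs
#' reference field), and the percent differences of the computed water dose
#' against the uncorrected and k-corrected pseudo-measurements. Cases with
#' `HI < hi_threshold` are flagged: at such homogeneity the correction
#' factor is expected within 1% of unity.
#'
#' @param case A [simulate_patient()] result (or a list with the same
#'   fields, for user-supplied data).
#' @param shell_margin_cm Shell margin around the chamber for COIN (cm).
#' @param frac_of_max Beam-intersection threshold, see
#'   [beam_intersects_chamber()].
#' @param hi_threshold HI flag level; default 0.05.
#' @param gap_threshold Open-leaf gap (cm) for complexity scoring.
#' @return An object of class `qa_report`: a list with one entry per mode
#'   (`rotated`, `collapsed`) plus plan-level fields.
#' @export
run_comparison <- function(case, shell_margin_cm = 1.5, frac_of_max = 0.25,
                           hi_threshold = 0.05, gap_threshold = 0.05) {
  spec <- case$config$spec
  cavity <- chamber_cylinder_mask(spec)
  contour <- chamber_contour_mask(spec)
  sphere <- chamber_sphere_mask(spec)
  shell <- expand_mask(contour, shell_margin_cm)
  ref_dose <- case$reference_beam_dose
  dw_ref <- mean(ref_dose$values[sphere$voxels])
  dair_ref <- mean(ref_dose$values[cavity$voxels])
  mcs <- plan_mcs(case$plan, gap_threshold = gap_threshold)

  mode_metrics <- function(beam_doses, measured) {
    total <- sum_beam_doses(beam_doses)
    dair <- mean(total$values[cavity$voxels])
    dw <- mean(total$values[sphere$voxels])
    k <- k_qclin(dw, dair, dw_ref, dair_ref)
    unc <- vapply(beam_doses, function(g) {
      if (is.null(g$rel_uncertainty_pct)) NA_real_ else g$rel_uncertainty_pct
    }, numeric(1))
    comb <- if (any(is.na(unc))) NA_real_ else combined_uncertainty(unc)
    hi <- homogeneity_index(total, contour)
    res <- list(
      hi = hi,
      coin = conformity_index(total, contour, shell),
      mcs_plan = mcs,
      intersection_fraction =
        intersection_fraction(beam_doses, contour, frac_of_max),
      chamber_mean_dose_gy = dair,
      water_sphere_dose_gy = dw,
      combined_uncertainty_pct = comb,
      k_qclin = as.numeric(k),
      hi_below_threshold = hi < hi_threshold)
    if (!is.null(measured) && is.finite(measured)) {
      corrected <- measured * res$k_qclin
      res$measured_gy <- measured
      res$diff_uncorrected_pct <- (dw - measured) / measured * 100
      res$diff_corrected_pct <- (dw - corrected) / corrected * 100
    }
    res
  }

  structure(
    list(plan_id = case$plan$plan_id,
         seed = case$seed,
         n_beams = length(case$plan$beams),
         mcs_plan = mcs,
         hi_threshold = hi_threshold,
         rotated = mode_metrics(case$rotated_beam_doses,
                                case$pseudo_measurement_rotated),
         collapsed = mode_metrics(case$collapsed_beam_doses,
                                  case$pseudo_measurement_collapsed)),
    class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("QA report for '", x$plan_id, "' (", x$n_beams, " beams, MCS ",
      format(x$mcs_plan, digits = 4), ")\n", sep = "")
  fmt <- function(m) {
    cat(sprintf("    HI %.4f%s | COIN %.3f | beams through chamber %.2f | k %.4f\n",
                m$hi, if (m$hi_below_threshold) "*" else " ",
                m$coin, m$intersection_fraction, m$k_qclin))
    if (!is.null(m$measured_gy))
      cat(sprintf("    vs measurement: uncorrected %+.2f%%, corrected %+.2f%%\n",
                  m$diff_uncorrected_pct, m$diff_corrected_pct))
  }
  cat("  rotated:\n"); fmt(x$rotated)
  cat("  collapsed:\n"); fmt(x$collapsed)
  cat("  (* HI below the", x$hi_threshold, "homogeneity flag)\n")
  invisible(x)
}

#' Simulate and analyze a synthetic QA cohort
#'
#' Generates `n_patients` seeded cases with [simulate_patient()] — beam
#' counts drawn uniformly from `beam_range` and per-patient modulation
#' depths from `modulation_range` (a cohort of mixed treatment sites spans
#' a range of plan complexities) — runs [run_comparison()] on each, and
#' returns the list of reports. Seeds are `seed + patient index`, so the
#' whole cohort is reproducible from one integer.
#'
#' @param n_patients Number of patients; default 20.
#' @param seed Base integer seed.
#' @param beam_range Inclusive range beams are drawn from; default 7 to 19.
#' @param modulation_range Range modulation depths are drawn from; a fixed
#'   `modulation` in `config` overrides the draw.
#' @param config Extra settings merged into [simulate_patient()]'s config.
#' @param ... Passed to [run_comparison()].
#' @return List of `qa_report` objects.
#' @export
simulate_cohort <- function(n_patients = 20, seed = 1,
                            beam_range = c(7, 19),
                            modulation_range = c(0.4, 0.8),
                            config = list(), ...) {
  stopifnot(n_patients >= 1)
  draws <- with_seed(seed, list(
    n_beams = sample(seq(beam_range[1L], beam_range[2L]), n_patients,
                     replace = TRUE),
    modulation = stats::runif(n_patients, modulation_range[1L],
                              modulation_range[2L])))
  lapply(seq_len(n_patients), function(i) {
    cfg <- utils::modifyList(
      list(n_beams = draws$n_beams[i], modulation = draws$modulation[i]),
      config)
    case <- simulate_patient(cfg, seed = seed + i)
    run_comparison(case, ...)
  })
}

#' Cohort summary of QA reports
#'
#' Per delivery mode, the mean and sample standard deviation (n-1) of the
#' percent differences between the computed water dose and the measurements
#' (uncorrected and k-corrected), the percent relative RMS difference for
#' both correction states, and the median HI. `NA` SD for a single report.
#'
#' @param reports Non-empty list of `qa_report` objects.
#' @return An object of class `qa_cohort` with a `summary` data frame and
#'   the per-report metric table `per_patient`.
#' @export
cohort_summary <- function(reports) {
  if (!is.list(reports) || length(reports) < 1L ||
      !all(vapply(reports, inherits, logical(1), "qa_report")))
    stop_imrtqa("reports must be a non-empty list of qa_report objects")
  per <- do.call(rbind, lapply(reports, function(r) {
    row <- function(mode) {
      m <- r[[mode]]
      data.frame(plan_id = r$plan_id, mode = mode, n_beams = r$n_beams,
                 mcs_plan = r$mcs_plan, hi = m$hi, coin = m$coin,
                 intersection_fraction = m$intersection_fraction,
                 k_qclin = m$k_qclin,
                 combined_uncertainty_pct = m$combined_uncertainty_pct,
                 measured_gy =
                   if (is.null(m$measured_gy)) NA_real_ else m$measured_gy,
                 computed_gy = m$water_sphere_dose_gy,
                 diff_uncorrected_pct =
                   if (is.null(m$diff_uncorrected_pct)) NA_real_
                   else m$diff_uncorrected_pct,
                 diff_corrected_pct =
                   if (is.null(m$diff_corrected_pct)) NA_real_
                   else m$diff_corrected_pct)
    }
    rbind(row("rotated"), row("collapsed"))
  }))
  summ <- do.call(rbind, lapply(split(per, per$mode), function(d) {
    sdv <- function(x) if (sum(is.finite(x)) >= 2L) stats::sd(x, na.rm = TRUE)
                       else NA_real_
    prms <- function(diff_pct) {
      ok <- is.finite(diff_pct)
      if (!any(ok)) return(NA_real_)
      sqrt(mean(diff_pct[ok]^2))
    }
    data.frame(
      mode = d$mode[1L], n = nrow(d),
      mean_diff_uncorrected_pct = mean(d$diff_uncorrected_pct, na.rm = TRUE),
      sd_diff_uncorrected_pct = sdv(d$diff_uncorrected_pct),
      mean_diff_corrected_pct = mean(d$diff_corrected_pct, na.rm = TRUE),
      sd_diff_corrected_pct = sdv(d$diff_corrected_pct),
      prms_uncorrected_pct = prms(d$diff_uncorrected_pct),
      prms_corrected_pct = prms(d$diff_corrected_pct),
      median_hi = stats::median(d$hi),
      max_abs_k_dev_pct = 100 * max(abs(d$k_qclin - 1)))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_patient = per), class = "qa_cohort")
}

#' @export
print.qa_cohort <- function(x, ...) {
  cat("QA cohort summary (", length(unique(x$per_patient$plan_id)),
      " patients)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.qa_cohort <- function(object, ...) object$summary

#' Plot homogeneity index against the correction factor deviation
#'
#' One point per patient and mode: chamber HI on the x axis, `|k - 1|` in
#' percent on the y axis, with the HI flag level and the 1% deviation line.
#'
#' @param x A `qa_cohort`.
#' @param hi_threshold HI reference line; default 0.05.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.qa_cohort <- function(x, hi_threshold = 0.05, ...) {
  d <- x$per_patient
  col <- ifelse(d$mode == "rotated", "steelblue", "firebrick")
  pch <- ifelse(d$mode == "rotated", 16, 17)
  graphics::plot(d$hi, 100 * abs(d$k_qclin - 1), col = col, pch = pch,
                 xlab = "Homogeneity index",
                 ylab = expression("|" * k[Qclin] - 1 * "| [%]"), ...)
  graphics::abline(v = hi_threshold, lty = 2)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topleft", legend = c("rotated", "collapsed"),
                   col = c("steelblue", "firebrick"), pch = c(16, 17),
                   bty = "n")
  invisible(x)
}

#' Write a cohort's tables to CSV/JSON
#'
#' @param cohort A [cohort_summary()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "qa_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "cohort_summary.csv")
  p2 <- file.path(dir, "per_patient.csv")
  p3 <- file.path(dir, "cohort_summary.json")
  utils::write.csv(cohort$summary, p1, row.names = FALSE)
  utils::write.csv(cohort$per_patient, p2, row.names = FALSE)
  writeLines(jsonlite::toJSON(cohort$summary, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA, na = "null"),
             p3)
  invisible(c(p1, p2, p3))
}
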