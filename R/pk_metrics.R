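# Noncompartmental metrics from a simulated (or synthetic) plasma profile:
# Cmax/Tmax with local quadratic refinement at the grid peak, trapezoidal
# AUCs with a log-linear terminal extrapolation for AUC(0-inf), and
# bioavailability as fraction of dose absorbed (the packaged compound is
# cleared renally with no first-pass loss).

#' Linear-trapezoid AUC on a time grid
#'
#' @param time_h Strictly increasing time grid, h.
#' @param conc Concentrations on the grid (ng/mL).
#' @param upper_h Upper integration limit, h; must lie within the grid.
#'   The profile is linearly interpolated at `upper_h` if it falls between
#'   grid points.
#' @return AUC in ng.h/mL.
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 1000, 0), 2) # triangle, 1000
#' @export
auc_trapezoid <- function(time_h, conc, upper_h) {
  if (length(time_h) != length(conc)) stop("time and concentration lengths differ")
  if (any(diff(time_h) <= 0)) stop("time grid must be strictly increasing")
  if (upper_h < time_h[1] || upper_h > time_h[length(time_h)]) {
    stop(sprintf("upper limit %.3g h outside the grid [%.3g, %.3g]",
                 upper_h, time_h[1], time_h[length(time_h)]))
  }
  keep <- time_h <= upper_h
  t_sub <- time_h[keep]
  c_sub <- conc[keep]
  if (t_sub[length(t_sub)] < upper_h) {
    c_up <- stats::approx(time_h, conc, xout = upper_h)$y
    t_sub <- c(t_sub, upper_h)
    c_sub <- c(c_sub, c_up)
  }
  sum(diff(t_sub) * (utils::head(c_sub, -1) + utils::tail(c_sub, -1)) / 2)
}

# Terminal slope (lambda_z, 1/h) from a log-linear fit over the last
# `n_tail` positive-concentration grid points; NA when the tail is flat zero.
terminal_lambda_z <- function(time_h, conc, n_tail = 12L) {
  pos <- conc > 0
  if (sum(pos) < 3L) return(NA_real_)
  idx <- utils::tail(which(pos), n_tail)
  if (length(idx) < 3L) return(NA_real_)
  fit <- stats::lm(log(conc[idx]) ~ time_h[idx])
  lz <- -unname(stats::coef(fit)[2])
  if (!is.finite(lz) || lz <= 0) NA_real_ else lz
}

#' Noncompartmental PK metrics from a simulation result
#'
#' Cmax and Tmax are taken from the output grid with a quadratic refinement
#' through the three points around the discrete peak (ties broken by the
#' earliest time); AUC(0-24) by linear trapezoid; AUC(0-inf) as the
#' trapezoid over the full horizon plus a log-linear tail extrapolation
#' C(t_end)/lambda_z; bioavailability as 100 x total absorbed / dose.
#'
#' @param result A `simulation_result` covering at least 24 h.
#' @param dose_mg Dose, mg (defaults to the dose recorded in `result`).
#' @param pk `pk_parameters` (defaults to those recorded in `result`).
#' @return A `pk_metrics` list: `cmax_ng_mL`, `tmax_h`, `auc_0_24_ng_h_mL`,
#'   `auc_0_inf_ng_h_mL`, `bioavailability_pct`.
#' @export
compute_metrics <- function(result, dose_mg = result$dose_mg, pk = result$pk) {
  time_h <- result$time_h
  conc <- result$plasma_conc_ng_mL
  if (max(time_h) < 24) stop("profile must cover at least 24 h")

  i <- which.max(conc)
  cmax <- conc[i]
  tmax <- time_h[i]
  if (cmax > 0 && i > 1 && i < length(conc)) {
    # vertex of the parabola through the three points around the peak
    t3 <- time_h[(i - 1):(i + 1)]
    c3 <- conc[(i - 1):(i + 1)]
    denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    a <- (t3[3] * (c3[2] - c3[1]) + t3[2] * (c3[1] - c3[3]) +
            t3[1] * (c3[3] - c3[2])) / denom
    b <- (t3[3]^2 * (c3[1] - c3[2]) + t3[2]^2 * (c3[3] - c3[1]) +
            t3[1]^2 * (c3[2] - c3[3])) / denom
    if (a < 0) {
      tv <- -b / (2 * a)
      if (tv >= t3[1] && tv <= t3[3]) {
        cv <- a * tv^2 + b * tv +
          (c3[1] - a * t3[1]^2 - b * t3[1])
        if (cv >= cmax) {
          tmax <- tv
          cmax <- cv
        }
      }
    }
  }

  auc24 <- auc_trapezoid(time_h, conc, 24)
  auc_end <- auc_trapezoid(time_h, conc, max(time_h))
  c_end <- conc[length(conc)]
  lz <- terminal_lambda_z(time_h, conc)
  tail_auc <- if (c_end > 0 && !is.na(lz)) c_end / lz else 0
  auc_inf <- auc_end + tail_auc

  f_pct <- 100 * sum(result$cumulative_absorbed_mg[nrow(result$cumulative_absorbed_mg), ]) /
    dose_mg

  structure(
    list(cmax_ng_mL = cmax, tmax_h = tmax,
         auc_0_24_ng_h_mL = auc24, auc_0_inf_ng_h_mL = auc_inf,
         bioavailability_pct = f_pct),
    class = "pk_metrics"
  )
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<pk_metrics>\n  Cmax  %8.1f ng/mL at Tmax %.2f h\n",
    "  AUC0-24 %8.0f ng.h/mL\n  AUC0-inf %7.0f ng.h/mL\n  F %14.2f %%\n"),
    x$cmax_ng_mL, x$tmax_h, x$auc_0_24_ng_h_mL, x$auc_0_inf_ng_h_mL,
    x$bioavailability_pct))
  invisible(x)
}

#' PK metrics for an intravenous-bolus verification run
#'
#' Convenience wrapper used in tests: metrics computed on a
#' `simulate_absorption(..., dose_to_central = TRUE)` result, for which
#' AUC(0-inf) must equal dose / (CL x BW) analytically.
#'
#' @param result A `simulation_result` from an IV-limit run.
#' @return `pk_metrics` (bioavailability is reported as NA: nothing was
#'   absorbed through the gut).
#' @export
iv_reference_metrics <- function(result) {
  m <- compute_metrics(result)
  m$bioavailability_pct <- NA_real_
  m
}
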