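.new_sensitivity_curve <- function(parameter, value, flow_error_percent,
                                   reference = NA_real_, units = "") {
  structure(data.frame(parameter = parameter, value = value,
                       flow_error_percent = flow_error_percent),
            class = c("sensitivity_curve", "data.frame"),
            reference = reference, units = units,
            max_error_percent = max(flow_error_percent))
}

#' Flow error from assuming a fixed FiO2 in the density
#'
#' When no FiO2 cell is available, the density is computed with a fixed
#' assumed FiO2 while the true mixture varies. Since the Venturi flow scales
#' as `rho^(-1/2)` and pressure and temperature cancel in the ratio, the
#' relative flow error is `|sqrt(rho(true) / rho(assumed)) - 1| * 100` —
#' equivalently the square root of the molar-mass ratio of the two mixtures.
#' Assuming 60% keeps the error within about 2.5% over the whole 21–100%
#' range with the default molar masses; assuming air only (21%) reaches about
#' 5.1% at 100% oxygen.
#'
#' @param assumed_fio2 the fixed FiO2 used for the density, percent.
#' @param true_fio2_grid true FiO2 values to sweep, percent, within
#'   \[21, 100\].
#' @param constants `gas_constants`.
#' @return A `sensitivity_curve` data.frame (`parameter`, `value` = true FiO2,
#'   `flow_error_percent`), with the maximum error as attribute
#'   `max_error_percent`.
#' @export
#' @examples
#' max(fio2_assumption_error(60)$flow_error_percent)  # ~2.5
fio2_assumption_error <- function(assumed_fio2,
                                  true_fio2_grid = seq(21, 100, by = 1),
                                  constants = gas_constants()) {
  stopifnot(assumed_fio2 >= 21, assumed_fio2 <= 100,
            all(true_fio2_grid >= 21), all(true_fio2_grid <= 100))
  m_of <- function(f) .density_si(f, 1, 1, constants)  # proportional to M_mix
  err <- abs(sqrt(m_of(true_fio2_grid) / m_of(assumed_fio2)) - 1) * 100
  .new_sensitivity_curve("true_fio2", true_fio2_grid, err,
                         reference = assumed_fio2, units = "%")
}

#' Flow error from omitting airway pressure in the density
#'
#' The cheap per-breath density uses atmospheric pressure only; the true
#' absolute pressure includes the airway gauge pressure. The resulting
#' relative flow error is `|1 - sqrt(p_atm / (p_atm + p_airway))| * 100`,
#' strictly increasing in airway pressure.
#'
#' @param p_atm_pa atmospheric pressure, Pa.
#' @param p_airway_grid_pa airway gauge pressures to sweep, Pa.
#' @return A `sensitivity_curve` (`value` = airway pressure, Pa).
#' @export
#' @examples
#' pressure_omission_error(81800, cmh2o_to_pa(seq(0, 30, 5)))
pressure_omission_error <- function(p_atm_pa,
                                    p_airway_grid_pa = cmh2o_to_pa(0:30)) {
  stopifnot(p_atm_pa > 0, all(p_airway_grid_pa >= 0))
  err <- abs(1 - sqrt(p_atm_pa / (p_atm_pa + p_airway_grid_pa))) * 100
  .new_sensitivity_curve("p_airway", p_airway_grid_pa, err,
                         reference = 0, units = "Pa")
}

#' One-at-a-time parameter sensitivity of the flow estimate
#'
#' Perturbs each model parameter by the given fractional amounts and
#' re-evaluates the flow equation (with the ideal-gas mixture density)
#' exactly — no finite-difference approximation — reporting the relative flow
#' error per parameter. Flow is linear in `cd` and `ac`, square-root in the
#' differential pressure, inverse-square-root in the density, so pressure and
#' temperature carry weight 1/2 while FiO2's weight is set by the molar-mass
#' contrast of air and oxygen.
#'
#' @param reference named list of reference values: `p_atm_pa`, `p_airway_pa`,
#'   `temp_k`, `fio2_percent`, `cd`, `ac_mm2`, `dps_pa`. The default airway
#'   pressure is a 5 cm H2O PEEP.
#' @param deltas fractional perturbations (e.g. 0.01 = +1%).
#' @param constants `gas_constants`.
#' @return Named list of `sensitivity_curve`s, one per parameter
#'   (`value` = fractional perturbation).
#' @export
#' @examples
#' s <- parameter_sensitivity(deltas = 0.01)
#' s$ac_mm2$flow_error_percent   # 1% : flow is linear in the port area
parameter_sensitivity <- function(reference = list(p_atm_pa = 81800,
                                                   p_airway_pa = 490.3325,
                                                   temp_k = 293.15,
                                                   fio2_percent = 21,
                                                   cd = 0.7, ac_mm2 = 58,
                                                   dps_pa = 100),
                                  deltas = seq(-0.05, 0.05, by = 0.005),
                                  constants = gas_constants()) {
  pars <- c("p_atm_pa", "p_airway_pa", "temp_k", "fio2_percent", "cd",
            "ac_mm2", "dps_pa")
  stopifnot(all(pars %in% names(reference)))

  q_of <- function(r) {
    rho <- .density_si(min(max(r$fio2_percent, 21), 100),
                       r$p_atm_pa + r$p_airway_pa, r$temp_k, constants)
    flow_from_dp(r$dps_pa, rho, venturi_geometry(r$cd, r$ac_mm2))
  }
  q_ref <- q_of(reference)

  curves <- lapply(pars, function(p) {
    err <- vapply(deltas, function(dl) {
      r <- reference
      r[[p]] <- r[[p]] * (1 + dl)
      abs(q_of(r) / q_ref - 1) * 100
    }, numeric(1))
    .new_sensitivity_curve(p, deltas, err, reference = reference[[p]],
                           units = "fraction")
  })
  names(curves) <- pars
  curves
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("Sensitivity curve for %s (%d points, reference %.6g %s): max flow error %.4g%%\n",
              x$parameter[1], nrow(x), attr(x, "reference"), attr(x, "units"),
              attr(x, "max_error_percent")))
  invisible(x)
}

#' Plot a sensitivity curve
#'
#' Base-graphics rendering of flow error against the swept value.
#'
#' @param x a `sensitivity_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sensitivity_curve <- function(x, ...) {
  graphics::plot(x$value, x$flow_error_percent, type = "l",
                 xlab = paste0(x$parameter[1], " (", attr(x, "units"), ")"),
                 ylab = "flow error (%)", ...)
  invisible(x)
}
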