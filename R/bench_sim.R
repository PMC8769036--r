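#' Virtual differential-pressure sensor model
#'
#' True transfer of the simulated D-Lite + DPS assembly: the inverse Venturi
#' relation evaluated with a flow-dependent discharge coefficient, plus an
#' additive offset, Gaussian noise and hard saturation. The default discharge
#' profile follows the reported behaviour of the original D-Lite piece — about
#' 0.75 in the 7–8 L/min region, falling towards 0.65 as the flow moves away —
#' as a piecewise-linear curve over configurable breakpoints, so calibration
#' is exercised against a truth that the fixed-cd runtime model cannot match
#' without the lookup table.
#'
#' @param cd_breakpoints data.frame with columns `flow_lpm` and `cd` defining
#'   the piecewise-linear discharge-coefficient profile over `|Q|` (held
#'   constant beyond the outermost breakpoints), or a function `|Q| -> cd`.
#' @param ac_mm2 true total port cross-section, mm^2.
#' @param noise_sd_pa additive Gaussian DPS noise, Pa.
#' @param offset_pa additive DPS offset, Pa.
#' @param saturation_pa hard clip of `|DPS|`, Pa (about the reading at
#'   80 L/min for the default geometry; `Inf` disables).
#' @return An object of class `sensor_model`.
#' @export
#' @examples
#' sensor_model()              # variable-cd truth, mild noise
#' sensor_model(cd_breakpoints = function(q) 0.7, noise_sd_pa = 0)  # ideal
sensor_model <- function(cd_breakpoints = NULL, ac_mm2 = 58,
                         noise_sd_pa = 0.05, offset_pa = 0,
                         saturation_pa = 650) {
  if (is.null(cd_breakpoints))
    cd_breakpoints <- data.frame(flow_lpm = c(0, 7, 8, 15),
                                 cd = c(0.65, 0.75, 0.75, 0.65))
  if (is.function(cd_breakpoints)) {
    cd_fun <- cd_breakpoints
    bp <- NULL
  } else {
    stopifnot(is.data.frame(cd_breakpoints),
              all(c("flow_lpm", "cd") %in% names(cd_breakpoints)))
    if (any(cd_breakpoints$cd <= 0) || any(cd_breakpoints$cd > 1))
      stop("cd values must lie in (0, 1]", call. = FALSE)
    bp <- cd_breakpoints
    cd_fun <- stats::approxfun(bp$flow_lpm, bp$cd, rule = 2)
  }
  stopifnot(ac_mm2 > 0, noise_sd_pa >= 0, saturation_pa > 0)
  structure(list(cd_fun = cd_fun, cd_breakpoints = bp,
                 ac_m2 = ac_mm2 * 1e-6, ac_mm2 = ac_mm2,
                 noise_sd_pa = noise_sd_pa, offset_pa = offset_pa,
                 saturation_pa = saturation_pa),
            class = "sensor_model")
}

#' Read the virtual sensor
#'
#' `dps = sign(Q) * Q^2 rho / (2 cd(|Q|)^2 ac^2) + offset + noise`, clipped at
#' the saturation limit. Noise is drawn from the current RNG stream; seed it
#' in the caller for reproducibility. With a constant cd profile and zero
#' noise and offset this degenerates exactly to [dp_from_flow()].
#'
#' @param q_lpm true flow, L/min (signed, vectorised).
#' @param model a `sensor_model`.
#' @param rho gas density at the sensor, kg/m^3 (scalar or per-sample vector).
#' @return Simulated DPS readings, Pa.
#' @export
virtual_sensor_read <- function(q_lpm, model, rho) {
  stopifnot(inherits(model, "sensor_model"))
  if (any(rho <= 0)) stop("rho must be positive", call. = FALSE)
  cd <- model$cd_fun(abs(q_lpm))
  q_si <- abs(q_lpm) / .LPM_PER_M3S
  dps <- sign(q_lpm) * q_si^2 * rho / (2 * cd^2 * model$ac_m2^2) +
    model$offset_pa
  if (model$noise_sd_pa > 0)
    dps <- dps + stats::rnorm(length(q_lpm), 0, model$noise_sd_pa)
  pmin(pmax(dps, -model$saturation_pa), model$saturation_pa)
}

#' Volume-control ventilation scenario
#'
#' Defines a square-flow volume-control waveform: constant inspiratory flow
#' `vt / t_insp`, passive exponential expiration whose integral matches the
#' delivered volume, airway pressure ramping from PEEP during inspiration and
#' relaxing back during expiration. The expiratory time constant is
#' `resistance * compliance` of a two-element lung model.
#'
#' @param vt_ml tidal volume, mL.
#' @param bpm breaths per minute.
#' @param ie_ratio inspiratory:expiratory time ratio, either a scalar I/E
#'   (1 means 1:1) or a length-2 vector `c(I, E)`.
#' @param peep_cmh2o PEEP, cm H2O.
#' @param fio2_percent constant FiO2 in percent, or a data.frame
#'   `(t_s, fio2_percent)` piecewise-constant schedule.
#' @param amb `ambient_conditions` of the run.
#' @param duration_s run length, s (default 5 ventilatory cycles).
#' @param dt_s sampling interval, s (default 5 ms).
#' @param compliance_ml_per_pa lung compliance, mL/Pa.
#' @param resistance_pa_per_l_s airway resistance, Pa/(L/s).
#' @return An object of class `ventilation_scenario`.
#' @export
#' @examples
#' ventilation_scenario(vt_ml = 600)  # 20 BPM, I:E 1:1, PEEP 5 cm H2O
ventilation_scenario <- function(vt_ml, bpm = 20, ie_ratio = 1,
                                 peep_cmh2o = 5, fio2_percent = 21,
                                 amb = ambient_conditions(),
                                 duration_s = NULL, dt_s = 0.005,
                                 compliance_ml_per_pa = 1,
                                 resistance_pa_per_l_s = 500) {
  if (length(ie_ratio) == 2) ie_ratio <- ie_ratio[1] / ie_ratio[2]
  stopifnot(vt_ml >= 0, bpm > 0, ie_ratio > 0, dt_s > 0,
            compliance_ml_per_pa > 0, resistance_pa_per_l_s >= 0,
            inherits(amb, "ambient_conditions"))
  t_cycle <- 60 / bpm
  if (is.null(duration_s)) duration_s <- 5 * t_cycle
  structure(list(vt_ml = vt_ml, bpm = bpm, ie_ratio = ie_ratio,
                 peep_cmh2o = peep_cmh2o, fio2_percent = fio2_percent,
                 amb = amb, duration_s = duration_s, dt_s = dt_s,
                 compliance_ml_per_pa = compliance_ml_per_pa,
                 resistance_pa_per_l_s = resistance_pa_per_l_s,
                 t_cycle_s = t_cycle,
                 t_insp_s = t_cycle * ie_ratio / (1 + ie_ratio)),
            class = "ventilation_scenario")
}

.fio2_at <- function(fio2_percent, t_s) {
  if (is.data.frame(fio2_percent)) {
    stopifnot(all(c("t_s", "fio2_percent") %in% names(fio2_percent)))
    idx <- findInterval(t_s, fio2_percent$t_s)
    fio2_percent$fio2_percent[pmax(idx, 1L)]
  } else {
    rep(fio2_percent, length(t_s))
  }
}

#' Generate the true ventilation waveform
#'
#' Deterministic time series of true flow, airway pressure and FiO2 for a
#' scenario (all randomness in the bench lives in the sensor noise, not the
#' waveform).
#'
#' @param scenario a `ventilation_scenario`.
#' @return data.frame with columns `t_s`, `true_flow_lpm` (signed, positive
#'   during inspiration), `p_airway_pa`, `fio2_percent`.
#' @export
generate_waveform <- function(scenario) {
  stopifnot(inherits(scenario, "ventilation_scenario"))
  sc <- scenario
  t <- seq(0, sc$duration_s, by = sc$dt_s)
  phase <- t %% sc$t_cycle_s
  insp <- phase < sc$t_insp_s - 1e-12
  t_exp_len <- sc$t_cycle_s - sc$t_insp_s
  tau <- sc$resistance_pa_per_l_s * sc$compliance_ml_per_pa / 1000  # s

  q <- numeric(length(t))
  p_drive <- sc$vt_ml / sc$compliance_ml_per_pa                     # Pa
  peep_pa <- cmh2o_to_pa(sc$peep_cmh2o)
  p_aw <- rep(peep_pa, length(t))

  if (sc$vt_ml > 0) {
    q_insp <- sc$vt_ml / sc$t_insp_s * 0.06                         # L/min
    q[insp] <- q_insp
    te <- phase[!insp] - sc$t_insp_s
    q0 <- sc$vt_ml / (tau * (1 - exp(-t_exp_len / tau)))            # mL/s
    q[!insp] <- -q0 * exp(-te / tau) * 0.06
    p_aw[insp] <- peep_pa + p_drive * phase[insp] / sc$t_insp_s
    p_aw[!insp] <- peep_pa + p_drive * exp(-te / tau)
  }

  data.frame(t_s = t, true_flow_lpm = q, p_airway_pa = p_aw,
             fio2_percent = .fio2_at(sc$fio2_percent, t))
}

#' Simulate a calibration session on the virtual bench
#'
#' Emits the (reference flow, averaged DPS reading) pairs that
#' [build_table()] consumes, using the air-only open-circuit density at the
#' calibration site (atmospheric pressure, no airway pressure). Each grid
#' point averages `n_avg` sensor readings, emulating the steady-flow capture
#' at each step of the protocol.
#'
#' @param model a `sensor_model` (the truth).
#' @param amb `ambient_conditions` at the calibration site.
#' @param flow_grid reference flows, L/min (default: the 48-point protocol).
#' @param seed integer seed for the sensor noise (NULL: current RNG state).
#' @param n_avg readings averaged per grid point.
#' @param constants `gas_constants`.
#' @return data.frame with columns `flow_lpm`, `dps_pa`.
#' @export
generate_calibration_run <- function(model, amb,
                                     flow_grid = protocol_flow_grid(),
                                     seed = NULL, n_avg = 100,
                                     constants = gas_constants()) {
  stopifnot(inherits(model, "sensor_model"),
            inherits(amb, "ambient_conditions"), n_avg >= 1)
  if (!is.null(seed)) set.seed(seed)
  rho <- gas_density(fio2_to_fractions(21), amb, constants,
                     include_airway_pressure = FALSE)
  dps <- vapply(flow_grid, function(q) {
    mean(virtual_sensor_read(rep(q, n_avg), model, rho))
  }, numeric(1))
  data.frame(flow_lpm = flow_grid, dps_pa = dps)
}

#' Closed-loop virtual-bench run
#'
#' Runs the full chain waveform -> virtual sensor -> lookup estimator ->
#' breath segmentation, and compares per-breath estimated volumes against the
#' scenario truth. The sensor sees the physically true density (actual FiO2,
#' atmospheric plus airway pressure at each sample); the estimator uses
#' whatever `density_mode` it is configured with, so the comparison includes
#' the density-approximation error a real deployment would incur.
#'
#' Breath boundaries are taken from the true flow signal and applied to both
#' series, so true and estimated volumes are integrated over identical
#' windows.
#'
#' @param scenario a `ventilation_scenario`.
#' @param model a `sensor_model`.
#' @param table a `calibration_table`.
#' @param geom assumed `venturi_geometry` of the estimator.
#' @param constants `gas_constants`.
#' @param density_mode estimator density mode, see [estimate_run()].
#' @param seed integer seed for the sensor noise.
#' @return An object of class `bench_result`: data.frame with one row per
#'   breath (`t_start_s`, `t_end_s`, `v_insp_true_ml`, `v_insp_est_ml`,
#'   `v_exp_true_ml`, `v_exp_est_ml`, `err_insp_percent`, `err_exp_percent`,
#'   `complete`); the estimated-flow run is attached as attribute `run`.
#' @export
run_virtual_bench <- function(scenario, model, table,
                              geom = venturi_geometry(),
                              constants = gas_constants(),
                              density_mode = c("per_breath", "per_sample",
                                               "off"),
                              seed = NULL) {
  density_mode <- match.arg(density_mode)
  stopifnot(inherits(scenario, "ventilation_scenario"),
            inherits(model, "sensor_model"),
            inherits(table, "calibration_table"))
  wf <- generate_waveform(scenario)
  amb <- scenario$amb
  rho_true <- .density_si(wf$fio2_percent, amb$p_atm_pa + wf$p_airway_pa,
                          amb$temp_k, constants)
  if (!is.null(seed)) set.seed(seed)
  dps <- virtual_sensor_read(wf$true_flow_lpm, model, rho_true)

  run <- data.frame(t_s = wf$t_s, dps_pa = dps, p_airway_pa = wf$p_airway_pa,
                    fio2_percent = wf$fio2_percent,
                    p_atm_pa = amb$p_atm_pa, temp_k = amb$temp_k)
  est <- suppressWarnings(
    estimate_run(run, table, geom, constants, density_mode))

  seg <- segment_breaths(wf$t_s, wf$true_flow_lpm)
  from <- match(seg$t_start_s, wf$t_s)
  to <- match(seg$t_end_s, wf$t_s)
  one <- function(i) {
    ii <- from[i]:to[i]
    tt <- wf$t_s[ii]
    qt <- wf$true_flow_lpm[ii] * .ML_S_PER_LPM
    qe <- est$q_lpm[ii] * .ML_S_PER_LPM
    vt_i <- .trapz(tt, pmax(qt, 0))
    ve_i <- .trapz(tt, pmax(qe, 0))
    vt_e <- abs(.trapz(tt, pmin(qt, 0)))
    ve_e <- abs(.trapz(tt, pmin(qe, 0)))
    data.frame(
      t_start_s = seg$t_start_s[i], t_end_s = seg$t_end_s[i],
      v_insp_true_ml = vt_i, v_insp_est_ml = ve_i,
      v_exp_true_ml = vt_e, v_exp_est_ml = ve_e,
      err_insp_percent = if (vt_i > 0) (ve_i - vt_i) / vt_i * 100 else NA_real_,
      err_exp_percent = if (vt_e > 0) (ve_e - vt_e) / vt_e * 100 else NA_real_,
      complete = seg$complete[i]
    )
  }
  out <- do.call(rbind, lapply(seq_len(nrow(seg)), one))
  class(out) <- c("bench_result", "data.frame")
  attr(out, "run") <- est
  out
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("Virtual DPS sensor: ac = %.4g mm^2, noise sd = %.3g Pa, offset = %.3g Pa, saturation = %.4g Pa\n",
              x$ac_mm2, x$noise_sd_pa, x$offset_pa, x$saturation_pa))
  if (!is.null(x$cd_breakpoints)) {
    cat("  cd profile breakpoints (flow L/min -> cd): ",
        paste(sprintf("%.3g->%.3g", x$cd_breakpoints$flow_lpm,
                      x$cd_breakpoints$cd), collapse = ", "), "\n")
  } else cat("  cd profile: user function\n")
  invisible(x)
}

#' @export
print.ventilation_scenario <- function(x, ...) {
  cat(sprintf("Volume-control scenario: VT %.4g mL, %g BPM, I:E %.3g:1, PEEP %.3g cm H2O, %.4g s at dt %.3g s\n",
              x$vt_ml, x$bpm, x$ie_ratio, x$peep_cmh2o, x$duration_s, x$dt_s))
  invisible(x)
}
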