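#' Dichotomic-search lookup of the model differential pressure
#'
#' Locates the raw DPS reading in the stored calibration array by binary
#' search over the (strictly increasing) first column, then linearly
#' interpolates the second column between the bracketing rows:
#' `dp = dp0 + (dps - dps0) / (dps1 - dps0) * (dp1 - dp0)`.
#' The search operates on `|dps|` and re-applies the sign, so the positive
#' calibration branch serves both inspiration and expiration.
#'
#' Out-of-range handling: below the first row the interpolation is anchored at
#' the physical zero point (0, 0); above the last row the last two rows are
#' extrapolated linearly and the `extrapolated` flag is set (sensor
#' saturation territory). A target equal to a stored key — including one hit
#' mid-search — returns that row's value exactly and terminates the search.
#' The midpoint convention is the lower midpoint, `(lo + hi) %/% 2`.
#'
#' @param table a `calibration_table`.
#' @param dps raw DPS reading, Pa, signed scalar.
#' @return An object of class `lookup_result`: list with `dp` (signed,
#'   interpolated model differential pressure, Pa), bracketing row indices
#'   `idx_lo`, `idx_hi` (equal when the target hits a stored key; `idx_lo = 0`
#'   means the zero anchor), `steps` (number of midpoint comparisons, at most
#'   `ceiling(log2(n))` for in-range targets) and `extrapolated`.
#' @export
#' @examples
#' amb <- ambient_conditions()
#' rho <- gas_density(fio2_to_fractions(21), amb)
#' g <- protocol_flow_grid()
#' tab <- build_table(data.frame(flow_lpm = g, dps_pa = dp_from_flow(g, rho)), amb)
#' lookup_dp(tab, 100)
lookup_dp <- function(table, dps) {
  stopifnot(inherits(table, "calibration_table"),
            is.numeric(dps), length(dps) == 1L, is.finite(dps))
  d <- table$dps_pa
  p <- table$dp_model_pa
  n <- length(d)
  x <- abs(dps)
  s <- sign(dps)

  res <- function(dp_abs, lo, hi, steps, extra) {
    structure(list(dp = s * dp_abs, idx_lo = lo, idx_hi = hi,
                   steps = steps, extrapolated = extra),
              class = "lookup_result")
  }

  if (x <= d[1]) {
    if (x == d[1]) return(res(p[1], 1L, 1L, 0L, FALSE))
    # zero anchor: interpolate between (0, 0) and the first row
    return(res(p[1] * x / d[1], 0L, 1L, 0L, FALSE))
  }
  if (x >= d[n]) {
    if (x == d[n]) return(res(p[n], n, n, 0L, FALSE))
    dp_abs <- p[n - 1] + (x - d[n - 1]) / (d[n] - d[n - 1]) * (p[n] - p[n - 1])
    return(res(dp_abs, n - 1L, n, 0L, TRUE))
  }

  lo <- 1L
  hi <- n
  steps <- 0L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    steps <- steps + 1L
    if (x == d[mid]) return(res(p[mid], mid, mid, steps, FALSE))
    if (x < d[mid]) hi <- mid else lo <- mid
  }
  dp_abs <- p[lo] + (x - d[lo]) / (d[hi] - d[lo]) * (p[hi] - p[lo])
  res(dp_abs, lo, hi, steps, FALSE)
}

#' Estimate flow for a single ventilation sample
#'
#' Pipeline for one sample: look up the model differential pressure for the
#' raw DPS reading, compute the gas-mixture density from the sample's FiO2 and
#' ambient state, then evaluate the Venturi flow equation with the assumed
#' geometry.
#'
#' @param sample a list or one-row data.frame with fields `dps_pa`,
#'   `p_airway_pa`, `fio2_percent`, `p_atm_pa`, `temp_k`.
#' @param table a `calibration_table`.
#' @param geom assumed `venturi_geometry`.
#' @param constants `gas_constants`.
#' @param density_mode `"per_breath"`/`"off"` (atmospheric pressure only) or
#'   `"per_sample"` (adds airway pressure to the absolute pressure).
#' @return Flow in L/min, signed consistently with `dps_pa`.
#' @export
estimate_flow <- function(sample, table, geom = venturi_geometry(),
                          constants = gas_constants(),
                          density_mode = c("per_breath", "per_sample", "off")) {
  density_mode <- match.arg(density_mode)
  lk <- lookup_dp(table, sample$dps_pa)
  p_abs <- sample$p_atm_pa +
    if (density_mode == "per_sample") sample$p_airway_pa else 0
  rho <- .density_si(sample$fio2_percent, p_abs, sample$temp_k, constants)
  flow_from_dp(lk$dp, rho, geom)
}

#' Estimate flow over a whole ventilation run
#'
#' Applies the lookup + density + Venturi pipeline to every sample of a run.
#' Density modes: `"per_breath"` (default) recomputes the density once per
#' ventilatory cycle — at each expiration-to-inspiration transition of the DPS
#' sign — from atmospheric pressure only, and holds it constant within the
#' cycle; `"per_sample"` recomputes it at every sample including the airway
#' pressure; `"off"` recomputes per sample from atmospheric pressure only.
#'
#' @param run data.frame with columns `t_s`, `dps_pa`, `p_airway_pa`,
#'   `fio2_percent`, `p_atm_pa`, `temp_k` (extra columns are carried through).
#' @inheritParams estimate_flow
#' @return The input data.frame with added columns `dp_pa` (looked-up model
#'   differential pressure), `rho_kg_m3`, `q_lpm` (estimated flow) and
#'   `extrapolated`. Warns once if any lookup extrapolated beyond the table.
#' @export
estimate_run <- function(run, table, geom = venturi_geometry(),
                         constants = gas_constants(),
                         density_mode = c("per_breath", "per_sample", "off")) {
  density_mode <- match.arg(density_mode)
  req <- c("t_s", "dps_pa", "p_airway_pa", "fio2_percent", "p_atm_pa", "temp_k")
  stopifnot(is.data.frame(run), all(req %in% names(run)))
  n <- nrow(run)
  if (n == 0L) stop("empty ventilation run", call. = FALSE)
  if (n > 1 && any(diff(run$t_s) <= 0))
    stop("t_s must be strictly increasing", call. = FALSE)

  lk <- lapply(run$dps_pa, lookup_dp, table = table)
  dp <- vapply(lk, `[[`, numeric(1), "dp")
  extra <- vapply(lk, `[[`, logical(1), "extrapolated")

  if (density_mode == "per_sample") {
    rho <- .density_si(run$fio2_percent, run$p_atm_pa + run$p_airway_pa,
                       run$temp_k, constants)
  } else if (density_mode == "off") {
    rho <- .density_si(run$fio2_percent, run$p_atm_pa, run$temp_k, constants)
  } else {
    starts <- c(TRUE, run$dps_pa[-1] > 0 & run$dps_pa[-n] <= 0)
    idx <- cumsum(starts)              # breath id per sample
    at <- which(starts)                # breath-start sample indices
    rho_b <- .density_si(run$fio2_percent[at], run$p_atm_pa[at],
                         run$temp_k[at], constants)
    rho <- rho_b[idx]
  }

  if (any(extra))
    warning(sum(extra), " sample(s) beyond the calibrated DPS range ",
            "(extrapolated; possible sensor saturation)")

  out <- run
  out$dp_pa <- dp
  out$rho_kg_m3 <- rho
  out$q_lpm <- flow_from_dp(dp, rho, geom)
  out$extrapolated <- extra
  out
}

# trapezoid of y(t) over the full series, same units as y * t
.trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Trapezoidal tidal-volume integration
#'
#' Cumulative trapezoidal integral of the flow series,
#' `V_k = V_{k-1} + dt * (Q_k + Q_{k-1}) / 2`, with the L/min-to-mL/s unit
#' conversion applied. Timestamps may be irregular.
#'
#' @param t_s time stamps, s, strictly increasing.
#' @param q_lpm flow, L/min (signed).
#' @return Cumulative volume in mL, same length as `t_s`, starting at 0.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.005)
#' tail(integrate_volume(t, rep(6, length(t))), 1)  # 100 mL
integrate_volume <- function(t_s, q_lpm) {
  stopifnot(is.numeric(t_s), is.numeric(q_lpm),
            length(t_s) == length(q_lpm))
  n <- length(t_s)
  if (n > 1 && any(diff(t_s) <= 0))
    stop("t_s must be strictly increasing", call. = FALSE)
  rate <- q_lpm * .ML_S_PER_LPM   # mL/s
  if (n < 2) return(numeric(n) * 0)
  c(0, cumsum(diff(t_s) * (rate[-1] + rate[-n]) / 2))
}

#' Segment a flow series into breaths
#'
#' Breaths are delimited at expiration-to-inspiration transitions: a breath
#' starts where the flow rises above the hysteresis threshold and stays there
#' for at least `min_duration_s` (comparable to the 1–20 L/min trigger-flow
#' band, so brief noise excursions do not start a breath). Within each breath
#' the inspired volume is the integral of the positive flow and the expired
#' volume the magnitude of the integral of the negative flow. A series with no
#' qualifying transition yields a single open breath.
#'
#' @param t_s time stamps, s, strictly increasing.
#' @param q_lpm flow, L/min (signed).
#' @param hysteresis_lpm inspiration-onset flow threshold, L/min.
#' @param min_duration_s minimum time above threshold to accept an onset, s.
#' @param fio2_percent optional FiO2 series for the per-breath mean.
#' @return A data.frame of class `breath_table` with one row per breath:
#'   `t_start_s`, `t_end_s`, `v_insp_ml`, `v_exp_ml`, `q_peak_lpm`
#'   (largest `|Q|`), `fio2_mean_percent`, and `complete` (FALSE for the final
#'   breath when the series ends before the next onset).
#' @export
segment_breaths <- function(t_s, q_lpm, hysteresis_lpm = 2,
                            min_duration_s = 0.05, fio2_percent = NULL) {
  stopifnot(is.numeric(t_s), is.numeric(q_lpm),
            length(t_s) == length(q_lpm), hysteresis_lpm >= 0)
  n <- length(t_s)
  if (n > 1 && any(diff(t_s) <= 0))
    stop("t_s must be strictly increasing", call. = FALSE)

  above <- q_lpm > hysteresis_lpm
  r <- rle(above)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_end <- run_start + r$lengths - 1L
  keep <- r$values & (t_s[run_end] - t_s[run_start] >= min_duration_s)
  onsets <- run_start[keep]

  # each breath spans from its onset to the next onset inclusive, so the
  # boundary sampling interval is split consistently between neighbours
  if (length(onsets) == 0L) {
    bounds <- data.frame(from = 1L, to = n, complete = FALSE)
  } else {
    from <- onsets
    to <- c(onsets[-1], n)
    complete <- c(rep(TRUE, length(onsets) - 1L), FALSE)
    bounds <- data.frame(from = from, to = to, complete = complete)
  }

  one <- function(i) {
    ii <- bounds$from[i]:bounds$to[i]
    q <- q_lpm[ii]
    tt <- t_s[ii]
    data.frame(
      t_start_s = tt[1],
      t_end_s = tt[length(tt)],
      v_insp_ml = .trapz(tt, pmax(q, 0) * .ML_S_PER_LPM),
      v_exp_ml = abs(.trapz(tt, pmin(q, 0) * .ML_S_PER_LPM)),
      q_peak_lpm = max(abs(q)),
      fio2_mean_percent = if (is.null(fio2_percent)) NA_real_
                          else mean(fio2_percent[ii]),
      complete = bounds$complete[i]
    )
  }
  out <- do.call(rbind, lapply(seq_len(nrow(bounds)), one))
  class(out) <- c("breath_table", "data.frame")
  out
}
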