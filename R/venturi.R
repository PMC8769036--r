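#' Venturi constriction geometry
#'
#' The D-Lite spirometer piece is modelled with a fixed discharge coefficient
#' `cd` and the total cross-sectional area of its three equal ports `ac`.
#' Method defaults are cd = 0.7 and ac = 58 mm^2; the residual flow dependence
#' of the real discharge coefficient is absorbed by the calibration table, not
#' by this object.
#'
#' @param cd discharge coefficient, dimensionless, in (0, 1].
#' @param ac_mm2 total port cross-section, mm^2.
#' @return An object of class `venturi_geometry` (area kept in m^2 internally).
#' @export
#' @examples
#' venturi_geometry()
venturi_geometry <- function(cd = 0.7, ac_mm2 = 58) {
  stopifnot(is.finite(cd), is.finite(ac_mm2))
  if (cd <= 0 || cd > 1) stop("cd must lie in (0, 1]", call. = FALSE)
  if (ac_mm2 <= 0) stop("ac_mm2 must be positive", call. = FALSE)
  structure(list(cd = cd, ac_mm2 = ac_mm2, ac_m2 = ac_mm2 * 1e-6),
            class = "venturi_geometry")
}

#' Venturi flow from differential pressure
#'
#' Forward Venturi model `|Q| = cd * ac * sqrt(2 |dP| / rho)`, evaluated in SI
#' and returned in L/min. The sign of the differential pressure carries
#' through to the flow, so inspiration and expiration are both handled by the
#' same geometry (odd extension).
#'
#' @param dp_pa differential pressure across the flow ports, Pa (signed,
#'   vectorised).
#' @param rho gas density, kg/m^3 (scalar or vector recycled against `dp_pa`).
#' @param geom a `venturi_geometry`.
#' @return Flow in L/min, signed, same length as `dp_pa`.
#' @seealso [dp_from_flow()] for the exact algebraic inverse.
#' @export
#' @examples
#' flow_from_dp(100, 1.2, venturi_geometry(0.7, 58))  # ~31.45 L/min
flow_from_dp <- function(dp_pa, rho, geom = venturi_geometry()) {
  stopifnot(inherits(geom, "venturi_geometry"), is.numeric(dp_pa),
            is.numeric(rho))
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("rho must be positive and finite", call. = FALSE)
  q_si <- geom$cd * geom$ac_m2 * sqrt(2 * abs(dp_pa) / rho)
  sign(dp_pa) * q_si * .LPM_PER_M3S
}

#' Differential pressure from Venturi flow
#'
#' Inverse Venturi model `dP = Q^2 rho / (2 cd^2 ac^2)`, sign-preserving.
#' This is the relation the calibration step uses to compute the
#' model-consistent differential pressure for each reference flow.
#'
#' @param q_lpm flow in L/min (signed, vectorised).
#' @inheritParams flow_from_dp
#' @return Differential pressure in Pa, signed.
#' @export
#' @examples
#' dp_from_flow(31.45, 1.2)  # ~100 Pa
dp_from_flow <- function(q_lpm, rho, geom = venturi_geometry()) {
  stopifnot(inherits(geom, "venturi_geometry"), is.numeric(q_lpm),
            is.numeric(rho))
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("rho must be positive and finite", call. = FALSE)
  q_si <- abs(q_lpm) / .LPM_PER_M3S
  sign(q_lpm) * q_si^2 * rho / (2 * geom$cd^2 * geom$ac_m2^2)
}

#' @export
print.venturi_geometry <- function(x, ...) {
  cat(sprintf("Venturi geometry: cd = %.3g, ac = %.4g mm^2\n", x$cd, x$ac_mm2))
  invisible(x)
}
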