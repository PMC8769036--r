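#' Physical constants for the gas-mixture density model
#'
#' Molar masses of dry air and oxygen and the universal gas constant, used by
#' [gas_density()]. Defaults are the standard values; all are overridable so
#' that instrument-specific constants can be dropped in.
#'
#' @param m_air_g_per_mol molar mass of dry air, g/mol.
#' @param m_o2_g_per_mol molar mass of O2, g/mol.
#' @param r_j_per_mol_k universal gas constant, J/(mol K).
#' @return An object of class `gas_constants`.
#' @export
#' @examples
#' gas_constants()
gas_constants <- function(m_air_g_per_mol = 28.97,
                          m_o2_g_per_mol = 31.999,
                          r_j_per_mol_k = 8.314) {
  stopifnot(m_air_g_per_mol > 0, m_o2_g_per_mol > 0, r_j_per_mol_k > 0)
  if (m_o2_g_per_mol <= m_air_g_per_mol)
    stop("molar mass of O2 must exceed that of air", call. = FALSE)
  structure(list(m_air_g_per_mol = m_air_g_per_mol,
                 m_o2_g_per_mol = m_o2_g_per_mol,
                 r_j_per_mol_k = r_j_per_mol_k),
            class = "gas_constants")
}

#' Ambient (and airway) pressure/temperature state
#'
#' @param p_atm_pa atmospheric pressure, Pa.
#' @param temp_k absolute temperature, K.
#' @param p_airway_pa airway gauge pressure, Pa (0 for an open circuit).
#' @return An object of class `ambient_conditions`.
#' @export
#' @examples
#' ambient_conditions(81800, 293.15)
ambient_conditions <- function(p_atm_pa = 101325, temp_k = 293.15,
                               p_airway_pa = 0) {
  stopifnot(is.finite(p_atm_pa), is.finite(temp_k), is.finite(p_airway_pa))
  if (p_atm_pa <= 0) stop("p_atm_pa must be positive", call. = FALSE)
  if (temp_k <= 0) stop("temp_k must be positive", call. = FALSE)
  if (p_airway_pa < -p_atm_pa)
    stop("p_airway_pa below absolute vacuum", call. = FALSE)
  structure(list(p_atm_pa = p_atm_pa, temp_k = temp_k,
                 p_airway_pa = p_airway_pa),
            class = "ambient_conditions")
}

#' Air/O2 volume fractions from FiO2
#'
#' Models the circuit gas as a two-component volumetric blend of air (21% O2)
#' and pure oxygen, so that `fio2 = (21 * v_air + 100 * v_o2) / 100`. FiO2 of
#' 21% is pure air, 100% is pure oxygen. Values slightly outside \[21, 100\]
#' are clamped with a warning; values outside \[0, 100\] are an error.
#'
#' @param fio2_percent fraction of inspired oxygen, percent.
#' @return An object of class `gas_composition` with fields `fio2_percent`,
#'   `v_air_percent` and `v_o2_percent` (summing to 100).
#' @seealso [fractions_to_fio2()] for the inverse, [gas_density()].
#' @export
#' @examples
#' fio2_to_fractions(21)   # pure air
#' fio2_to_fractions(60)   # ~50.6% air, ~49.4% O2 by volume
fio2_to_fractions <- function(fio2_percent) {
  stopifnot(is.numeric(fio2_percent), length(fio2_percent) == 1L,
            is.finite(fio2_percent))
  tol <- 1e-9
  if (fio2_percent < -tol || fio2_percent > 100 + tol)
    stop("fio2_percent must lie in [0, 100], got ", fio2_percent,
         call. = FALSE)
  if (fio2_percent < 21) {
    warning("fio2_percent ", fio2_percent, " below 21 (air); clamped to 21")
    fio2_percent <- 21
  } else if (fio2_percent > 100) {
    fio2_percent <- 100
  }
  v_o2 <- (fio2_percent - 21) / (100 - 21) * 100
  structure(list(fio2_percent = fio2_percent,
                 v_air_percent = 100 - v_o2,
                 v_o2_percent = v_o2),
            class = "gas_composition")
}

#' Recompose FiO2 from a gas composition
#'
#' Exact inverse of [fio2_to_fractions()] under the linear two-component
#' mixing model.
#'
#' @param comp a `gas_composition`.
#' @return FiO2 in percent.
#' @export
fractions_to_fio2 <- function(comp) {
  stopifnot(inherits(comp, "gas_composition"))
  (21 * comp$v_air_percent + 100 * comp$v_o2_percent) / 100
}

# Vectorised mixture density core shared by the estimator and the bench.
# fio2 in percent, p_abs in Pa, temp in K; returns kg/m^3.
.density_si <- function(fio2_percent, p_abs_pa, temp_k, constants) {
  v_o2 <- pmin(pmax((fio2_percent - 21) / 79 * 100, 0), 100)
  v_air <- 100 - v_o2
  m_mix_kg <- (v_air * constants$m_air_g_per_mol +
                 v_o2 * constants$m_o2_g_per_mol) / 100 / 1000
  p_abs_pa * m_mix_kg / (constants$r_j_per_mol_k * temp_k)
}

#' Ideal-gas density of the air/O2 mixture
#'
#' Density is `rho = P_abs * M_mix / (R * T)` with `M_mix` the volume-weighted
#' molar mass of the air/oxygen blend. Absolute pressure is atmospheric
#' pressure, optionally plus airway gauge pressure when
#' `include_airway_pressure = TRUE` (per-sample density mode; the cheaper
#' per-breath mode freezes density at atmospheric pressure only).
#'
#' @param comp a `gas_composition`, see [fio2_to_fractions()].
#' @param amb an `ambient_conditions`.
#' @param constants a `gas_constants`.
#' @param include_airway_pressure add `p_airway_pa` to the absolute pressure?
#' @return Gas density in kg/m^3.
#' @export
#' @examples
#' gas_density(fio2_to_fractions(21), ambient_conditions(101325, 273.15))
gas_density <- function(comp, amb, constants = gas_constants(),
                        include_airway_pressure = FALSE) {
  stopifnot(inherits(comp, "gas_composition"),
            inherits(amb, "ambient_conditions"),
            inherits(constants, "gas_constants"))
  p_abs <- amb$p_atm_pa + if (include_airway_pressure) amb$p_airway_pa else 0
  if (p_abs <= 0) stop("absolute pressure must be positive", call. = FALSE)
  if (amb$temp_k <= 0) stop("temperature must be positive", call. = FALSE)
  .density_si(comp$fio2_percent, p_abs, amb$temp_k, constants)
}

#' @export
print.gas_composition <- function(x, ...) {
  cat(sprintf("Gas composition: FiO2 %.4g%% (air %.4g%%, O2 %.4g%% by volume)\n",
              x$fio2_percent, x$v_air_percent, x$v_o2_percent))
  invisible(x)
}
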