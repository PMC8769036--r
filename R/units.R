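# Internal unit conventions: all physics in SI (Pa, K, kg/m^3, m^2, m^3/s).
# Clinical units (L/min, cm H2O, mL, mm^2) appear only at the boundaries.

.PA_PER_CMH2O <- 98.0665
.LPM_PER_M3S <- 60000
.ML_S_PER_LPM <- 1000 / 60

#' Convert between cm H2O and pascal
#'
#' Clinical airway pressures are quoted in cm H2O; all internal computation is
#' in pascal. 1 cm H2O = 98.0665 Pa.
#'
#' @param x pressure values to convert.
#' @return Converted numeric vector.
#' @export
cmh2o_to_pa <- function(x) x * .PA_PER_CMH2O

#' @rdname cmh2o_to_pa
#' @export
pa_to_cmh2o <- function(x) x / .PA_PER_CMH2O
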