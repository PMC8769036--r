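Package: dliteflow
Title: Venturi Spirometry Flow Estimation by Calibration-Table Lookup with Dichotomic Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flow and tidal-volume estimation for mechanical ventilation with a
    D-Lite (Venturi-effect) spirometer piece. Instead of a global regression,
    a calibration procedure stores a two-column lookup array mapping raw
    differential-pressure-sensor readings to model-consistent differential
    pressures; at run time a dichotomic (binary) search plus linear
    interpolation recovers the pressure to enter into the Venturi flow
    equation, with FiO2-aware ideal-gas density correction and trapezoidal
    tidal-volume integration. Includes a synthetic virtual bench (ventilation
    waveform generator and virtual sensor with a flow-dependent discharge
    coefficient) so calibration and estimation can be exercised end-to-end
    without hardware, plus closed-form error-sensitivity sweeps for the
    density and flow model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
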