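# dliteflow

Flow and tidal-volume estimation for mechanical ventilation with a D-Lite
(Venturi-effect) spirometer piece, for developers and validators of
ventilation measurement systems.

A D-Lite piece placed proximal to the patient produces a differential
pressure ΔP across its constriction, ideally related to flow by

    Q = Cd · Ac · sqrt(2 ΔP / ρ),        ΔP = Q² ρ / (2 Cd² Ac²)

with discharge coefficient Cd, port cross-section Ac and gas density ρ. In
reality Cd varies with flow, which makes a single fitted constant inaccurate
exactly in the low-flow band (1–20 L/min) used to trigger assisted breaths.
This package implements the lookup-table alternative to regression:

* **Calibration** (`build_table()`): against a reference flow source with air
  only, store a two-column array pairing each *measured* sensor reading (DPS)
  with the *model-consistent* ΔP from the inverse equation at Cd = 0.7,
  Ac = 58 mm²; the protocol grid is 1–40 L/min in 1 L/min steps then 5 L/min
  steps to sensor saturation (~80 L/min), 48 rows.
* **Estimation** (`lookup_dp()`, `estimate_run()`): a dichotomic (binary)
  search — at most 6 midpoint comparisons for 48 rows — brackets the raw
  reading, linear interpolation recovers ΔP, and the forward equation with
  the FiO₂-aware ideal-gas mixture density returns flow; trapezoidal
  integration (`integrate_volume()`, `segment_breaths()`) gives per-breath
  inspired/expired volumes.
* **Virtual bench** (`sensor_model()`, `ventilation_scenario()`,
  `run_virtual_bench()`): a synthetic volume-control waveform generator and a
  virtual sensor whose true transfer uses a flow-dependent Cd (0.75 around
  7–8 L/min falling to 0.65) plus noise/offset/saturation, so the whole chain
  is testable end-to-end without hardware.
* **Error budget** (`fio2_assumption_error()`, `pressure_omission_error()`,
  `parameter_sensitivity()`): closed-form sensitivity of the flow estimate to
  FiO₂ assumptions, omitted airway pressure, and each model parameter.

## Worked example

Calibrate against the virtual bench at 81 800 Pa (a high-altitude site),
then run a 500 mL volume-control scenario closed loop:

```r
library(dliteflow)

amb    <- ambient_conditions(p_atm_pa = 81800, temp_k = 293.15)
sensor <- sensor_model()                       # variable-Cd truth, mild noise
cal    <- generate_calibration_run(sensor, amb, seed = 42)
tab    <- build_table(cal, amb)
validate_table(tab)
#> Calibration table report: 48 rows, DPS 0.0926 to 608.1 Pa
#>   DPS strictly increasing: TRUE; dp_model non-decreasing: TRUE (0 violation(s))
#>   adjustment factor dp_model/DPS: 0.8618 to 1.15 (median 0.8623)
```

The adjustment factors are the per-row intrinsic corrections the table
encodes: ≈(0.7/0.75)² = 0.862 where the true Cd sits on its 0.75 plateau,
above 1 where it has fallen towards 0.65. A raw reading of 100 Pa is mapped
to ΔP = 86.2 Pa before entering the flow equation:

```r
lookup_dp(tab, 100)$dp
#> [1] 86.22763

sc  <- ventilation_scenario(vt_ml = 500, bpm = 20, ie_ratio = 1,
                            peep_cmh2o = 5, amb = amb, duration_s = 15)
res <- run_virtual_bench(sc, sensor, tab, seed = 42)
round(res[res$complete, c("v_insp_true_ml", "v_insp_est_ml",
                          "err_insp_percent")], 2)
#>   v_insp_true_ml v_insp_est_ml err_insp_percent
#> 1            500        502.30             0.46
#> 2            500        502.28             0.46
#> 3            500        502.29             0.46
#> 4            500        502.30             0.46
```

Each simulated breath's inspired volume is recovered to well within the
±10% margin required of ventilator volume measurement; the residual ~0.5%
comes mostly from the per-breath density mode ignoring airway pressure. And
if no FiO₂ cell is available, assuming a constant 60% bounds the
density-induced flow error over the whole 21–100% FiO₂ range:

```r
attr(fio2_assumption_error(60), "max_error_percent")
#> [1] 2.486171
```

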