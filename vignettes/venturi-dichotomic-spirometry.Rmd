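---
title: "Venturi spirometry by calibration-table lookup: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Venturi spirometry by calibration-table lookup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dliteflow)
```

## The measurement problem

A D-Lite spirometer piece sits proximal to the patient in a mechanical
ventilation circuit. Flow through its Venturi constriction produces a
differential pressure between two ports, read by a differential pressure
sensor (DPS). The ideal relation is

$$ Q = C_d \, A_c \sqrt{\frac{2\,\Delta P}{\rho}} , \qquad
   \Delta P = \frac{Q^2 \rho}{2 C_d^2 A_c^2} , $$

with discharge coefficient $C_d$, total port cross-section $A_c$, and gas
density $\rho$. Two things make the ideal relation insufficient in practice:

* $C_d$ is not constant — for the D-Lite geometry it peaks around 0.75 in the
  7–8 L/min region and falls towards 0.65 away from it — so a single global
  regression constant misestimates low flows, exactly the range (1–20 L/min)
  used as the trigger for assisted breaths;
* $\rho$ depends on the air/O$_2$ mix (FiO$_2$), on atmospheric pressure
  (hence altitude) and on temperature, and FiO$_2$ changes during ventilation.

The method implemented here fixes $C_d = 0.7$ and $A_c = 58$ mm$^2$ and
absorbs everything the fixed constants get wrong into a stored **calibration
table**: for each reference flow of an air-only calibration session, the
table pairs the *measured* DPS reading with the *model-consistent*
$\Delta P$ from the inverse relation above. At run time a dichotomic (binary)
search locates the raw reading between two stored rows and linear
interpolation

$$ \Delta P = \Delta P_0 +
   \frac{\mathrm{DPS}-\mathrm{DPS}_0}{\mathrm{DPS}_1-\mathrm{DPS}_0}
   (\Delta P_1 - \Delta P_0) $$

recovers the pressure to feed into the forward flow equation. Errors are
therefore *local* — confined to one inter-row segment — rather than global as
with a fitted regression. Tidal volume follows by trapezoidal integration
$V_k = V_{k-1} + \Delta t (Q_k + Q_{k-1})/2$.

## Gas density model

Density is the ideal-gas value with a volume-weighted molar mass:

$$ \rho = \frac{P_\mathrm{abs}}{R\,T}\cdot
   \frac{\%V_\mathrm{Air}\, m_\mathrm{Air} + \%V_{O_2}\, m_{O_2}}{100} . $$

The circuit gas is modelled as a two-component volumetric blend of air
(21% O$_2$) and pure oxygen, so $\%V_{O_2} = (\mathrm{FiO_2}-21)/79 \times
100$; this is the unique linear mapping consistent with the pure-air and
pure-oxygen endpoints. Defaults are $m_\mathrm{Air} = 28.97$ g/mol,
$m_{O_2} = 31.999$ g/mol, $R = 8.314$ J/(mol·K), all overridable through the
configuration (`gas.*` keys) for instrument-specific constants. Humidity,
CO$_2$ content and non-ideal behaviour are out of scope.

Absolute pressure is atmospheric plus, optionally, the airway gauge pressure.
Three density modes are offered (`density.airway_pressure_mode`):

* `per_breath` (default): density frozen at each expiration-to-inspiration
  transition, atmospheric pressure only — one density per ventilatory cycle,
  the cheap mode suited to an embedded loop;
* `per_sample`: recomputed every sample including airway pressure — the most
  faithful, at more arithmetic per step;
* `off`: per-sample but atmospheric only.

Omitting the airway pressure costs
$|1-\sqrt{P_\mathrm{atm}/(P_\mathrm{atm}+P_\mathrm{aw})}|$ in relative flow,
about 1.8% at 30 cm H$_2$O over 81 800 Pa — `pressure_omission_error()`
computes the curve.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `venturi.cd` | 0.7 | — | assumed discharge coefficient; residual variation absorbed by the table |
| `venturi.ac_mm2` | 58 | mm$^2$ | total cross-section of the three ports |
| `sampling.dt_s` | 0.005 | s | estimation period; integration accepts irregular stamps anyway |
| `breaths.hysteresis_lpm` | 2 | L/min | inspiration-onset threshold, inside the 1–20 L/min trigger band |
| `breaths.min_duration_s` | 0.05 | s | onset must persist this long, rejects noise blips |
| calibration grid | 1–40 by 1, 45–80 by 5 | L/min | dense at low flow where trigger accuracy matters; 48 points to sensor saturation |

All internal computation is SI (Pa, K, kg/m$^3$); the clinical units
(L/min, cm H$_2$O, mL) are converted at the boundaries (1 cm H$_2$O =
98.0665 Pa, 1 m$^3$/s = 60 000 L/min). The printed form of the forward flow
equation in the source literature mixes unit systems and is not dimensionally
closed as written; committing to SI internally makes every step unit-testable.

## Numerical choices in the lookup

* **Midpoint convention**: lower midpoint, `(lo + hi) %/% 2`. Only the
  logarithmic step bound (6 comparisons for a 48-row table) is guaranteed,
  not a particular visited-index sequence — published worked examples imply a
  midpoint convention only loosely, so the exact path is unspecified here.
* **Ties**: a target equal to a stored key, including one hit mid-search,
  returns that row's value exactly and stops.
* **Below range**: interpolation is anchored at the physical zero (0, 0), so
  zero reading maps to zero flow.
* **Above range**: linear extrapolation from the last two rows with an
  `extrapolated` flag — this is sensor-saturation territory (~80 L/min) and
  readings there are suspect.
* **Expiration**: the table stores the positive (air-only, inspiratory-range)
  branch; the lookup operates on $|$DPS$|$ and re-applies the sign. Whether a
  separate expiratory calibration would differ is untested hardware-side;
  mirroring is a documented assumption.
* **Duplicate keys**: calibration readings within 0.01 Pa (the DPS
  offset-stability scale) merge by averaging, since the search needs strictly
  increasing keys.

## The virtual bench

`sensor_model()` + `ventilation_scenario()` + `run_virtual_bench()` form a
synthetic test bench so the whole chain — calibrate, search, interpolate,
density-correct, integrate, segment — runs end-to-end with no hardware.

The **virtual sensor** applies the inverse Venturi relation with a
*flow-dependent* discharge coefficient, plus offset, Gaussian noise and hard
saturation. The default $C_d$ profile is piecewise linear through
(0, 0.65) → (7, 0.75) → (8, 0.75) → (15, 0.65), constant outside: a smooth
reading of the reported "0.75 at 7–8 L/min, decreasing to 0.65 away from it"
behaviour. The phrasing is ambiguous about how fast the decay happens, so the
breakpoints are fully configurable and alternative readings plug in. Noise
defaults to 0.05 Pa (a fraction of the ~1.3 Pa reading at 4 L/min);
calibration averages 100 readings per grid point, emulating steady-flow
capture.

The **waveform** is square-flow volume control: constant inspiratory flow
$V_T/t_\mathrm{insp}$, passive exponential expiration with time constant
$\tau = R_\mathrm{aw} C$ and amplitude chosen so the continuous-time expired
integral matches $V_T$; airway pressure ramps linearly from PEEP during
inspiration and relaxes exponentially back. Defaults $R_\mathrm{aw} = 500$
Pa/(L/s) and $C = 1$ mL/Pa give $\tau = 0.5$ s and peak expiratory flows of
roughly 13–100 L/min over the 100–800 mL sweep — clinically plausible for a
passive test lung. (A literal reading of one published bench description
would give a compliance thousands of times larger and an hour-long time
constant; that is treated as a typographical artifact and replaced by a
physically sensible default.) The simulation deliberately omits AMBU actuator
mechanics, patient effort and leaks: passing the closed-loop margin here
shows the estimator chain is self-consistent under realistic waveforms and a
mismatched $C_d$ truth, not that any physical rig meets it.

One discretisation note: with a discontinuous flow at the
inspiration/expiration switch, the trapezoid of the sign-clipped sampled
series differs from the continuous integral by about half a sample at the
jump (~0.5% of $V_T$ on the expired side at 5 ms). Breath windows run from
each onset to the next onset *inclusive*, which makes the inspired-side
accounting exact for the square waveform; true and estimated volumes are
always integrated over identical windows, so closed-loop error comparisons
never see this artifact.

Breath segmentation triggers on the flow rising above 2 L/min for at least
50 ms. A breath whose flow genuinely dips below the threshold mid-inspiration
would be split — acceptable for bench waveforms, a known limitation for
spontaneous-effort signals.

All bench randomness is Gaussian sensor noise drawn after a single explicit
seed; identical seeds give bit-identical outputs.

## Error-budget sweeps

`fio2_assumption_error()`, `pressure_omission_error()` and
`parameter_sensitivity()` evaluate the closed-form error model — the
$\rho^{-1/2}$ and $C_d A_c \sqrt{\Delta P}$ dependencies re-evaluated
exactly, no finite differences, and no lookup-table stage (they quantify the
*model's* sensitivities, not a particular calibration). Two results worth
remembering, both computed by the test suite and the acceptance script:

* with **no FiO$_2$ cell**, assuming a constant 60% keeps the flow error
  within ~2.5% over the whole 21–100% range (the worst case assuming air
  only is ~5.1%, at pure oxygen: $\sqrt{m_{O_2}/m_\mathrm{Air}}-1$);
* among the density parameters, absolute **pressure** (and temperature,
  which enters with the same magnitude-½ exponent) dominates FiO$_2$ per
  unit fractional perturbation.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the FiO$_2$ sweeps at 1%
steps (80 points), the lookup-vs-linear-scan equivalence on 1000 random
monotone tables, and the closed-loop bench at 15 tidal volumes (100–800 mL
in 50 mL steps), 15 s of simulated ventilation each at 5 ms sampling —
four complete breaths per volume, 60 scored breaths in total. These sizes
exercise every code path while keeping a full run in seconds.

## Known limitations

* The calibration table linearises between rows; between the 5 L/min-spaced
  high-flow rows the quadratic transfer is approximated to ~0.3% in
  $\Delta P$ (~0.15% in flow).
* The FiO$_2$ blend model ignores humidity and CO$_2$; at body temperature
  and saturation this biases density by a few percent of the correction.
* The mirrored expiratory lookup assumes a symmetric device transfer.
* `per_breath` density uses the FiO$_2$ and pressures at the onset sample; a
  mid-breath FiO$_2$ step is only picked up at the next cycle.
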