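---
title: "A zonal surrogate for forced-air precooling of packaged strawberries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A zonal surrogate for forced-air precooling of packaged strawberries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precoolr)
```

## The problem

Strawberries must be cooled from field temperature (~16 °C) to near storage
temperature within hours of harvest; the benchmark is the *7/8th cooling
time*, the time for the fruit–air temperature difference to fall to 1/8 of
its initial value. In forced-air (suction) precooling, cold room air at
1 °C and 80 % RH is pulled through vented packages on a tray, and the vent
and tray layout decides both how fast and how uniformly the fruit cool.
`precoolr` simulates a two-package tray under four vent layouts — a parallel
airflow system (PAS), the same system with a vented airflow restriction
plate (MPAS), a relocated solid plate (ARP-M1), and an improved layout with
extra end-wall vents (IPAS) — and quantifies cooling time, cooling
heterogeneity, and transpiration moisture loss.

## Model structure

The package deliberately replaces conjugate CFD (a resolved laminar flow
field around every fruit) with a desk-scale **zonal surrogate**:

* **Airflow.** Each package is split at the mid-plane normal to the main
  flow direction into a *first half* and a *second half* zone. In
  `prescribed` mode (the default and the mode used for all headline
  numbers), per-package and per-half flow fractions are replayed from each
  design's split table. An `orifice` mode solves node pressures on the
  vent graph with the discharge law $Q = C_d A \sqrt{2\Delta P/\rho}$
  ($C_d = 0.61$, sharp-edged); it is exploratory and is *not* expected to
  reproduce the tabulated splits, which came from CFD.
* **Fruit.** All fruits in a zone are identical spheres (diameter
  $d = 0.03$ m, $k_p = 0.57$ W m⁻¹ K⁻¹, $c_{p,p} = 3950$ J kg⁻¹ K⁻¹,
  $\rho_p = 800$ kg m⁻³) solved by 1-D radial conduction on a
  finite-volume grid (10 shells by default; doubling the grid moves the
  7/8th time by < 1 %, which the suite checks).
* **Air zones.** Each zone is a well-mixed air volume:
  $\rho_a V c_{p,a} \,dT_a/dt = \sum \dot m\, c_{p,a} (T_{in} - T_a) +
  \sum h A (T_s - T_a)$. Zones are chained along the design's directed
  vent graph; for IPAS, 22 % of the total flow reaches package 2 as
  package-1 exhaust and 3.24 % reaches package 1 directly from the cold
  room through the extra vents.
* **Surface coupling.** The surrogate has no surface-resolved flow field,
  so the convective coefficient comes from the heat–mass analogy applied
  to the mass-transfer correlation with Prandtl replacing Schmidt:
  $\mathrm{Nu} = 2 + 0.522\,\mathrm{Re}^{0.53}\mathrm{Pr}^{0.33}$,
  $h = \mathrm{Nu}\,k_a/d$ (≈ 4.7 W m⁻² K⁻¹ at the in-package
  $\mathrm{Re} \approx 54$).

## The transpiration submodel

With the moisture flag on, the fruit surface boundary condition gains the
evaporative sink $\dot m L$:

$$\dot m = k_g (p_s - p_a), \qquad
  p_s = \mathrm{VPL} \cdot p_w(T_s), \qquad
  p_a = \mathrm{RH} \cdot p_w(T_a),$$

with $p_w(T) \approx \exp(23.4795 - 3990.5/(T + 233.833))$ (T in °C),
latent heat $L = 9.1\,T^2 - 7512.9\,T + 3875.1\times10^3$ (T in kelvin),
and the film/skin resistances in series,
$1/k_g = 1/k_{g,conv} + 1/k_{g,skin}$. The film coefficient follows
$\mathrm{Sh} = 2 + 0.522\,\mathrm{Re}^{0.53}\mathrm{Sc}^{0.33}$,
$k_m = \mathrm{Sh}\,D/d$,
$k_{g,conv} = \rho_a M_{H_2O}/(M_a p_{atm})\,k_m$.

Three numerical conventions matter and are pinned by tests:

* **Units.** The latent-heat polynomial takes kelvin (2.502 MJ kg⁻¹ at
  0 °C, within 0.1 % of steam tables; a Celsius reading misses by > 50 %),
  while the saturation-pressure correlation takes Celsius (611 Pa at 0 °C).
  Internal state is Celsius for temperatures with each formula converting
  at its boundary.
* **Correlation coefficient.** The Sherwood coefficient is 0.522 exactly as
  used here (not the 0.552 of the classical single-sphere correlation); it
  is exposed in the defaults file for sensitivity work.
* **Sign.** A negative driving force ($p_a > p_s$) is clamped to zero flux
  by default — condensation is not modelled — with an opt-in `signed` mode.

Defaults that the literature does not fix numerically are set once in
`inst/extdata/defaults.yaml`: VPL = 0.99 (near-saturated fresh tissue),
$k_{g,skin} = 5.5\times10^{-8}$ s m⁻¹ (strawberry-class cuticle permeance),
and dry-air properties at 0 °C.

## Study conditions and calibrations

The fixed conditions are 16 °C initial fruit, 1 °C / 80 % RH air, and a
specific airflow of 0.4 L s⁻¹ per kg of product. Quantities that the vent
layouts do not determine numerically are package-level calibrations, chosen
once and kept:

* package product mass 1.0 kg (total 2 kg, so total flow
  `total_airflow(0.4, 2)` = 8×10⁻⁴ m³ s⁻¹), 88 fruits per package;
* package outer surface area 0.0833 m², back-solved so the base vent set
  (26 lateral + 9 lid vents) opens 28.2 % of the package area and the six
  extra IPAS vents (0.004 m² per package) raise it to 33 %;
* zone cross-section 0.00835 m², calibrated once so that default IPAS
  throughputs give an in-package Reynolds number of ~54;
* zone free-air volume 6.25×10⁻⁴ m³ (≈ 50 % packing porosity).

## Integration and conservation

The coupled system (4 zones × 10 shells + 4 air states + bookkeeping
integrals) is integrated with `deSolve::ode` (lsoda, rtol = atol = 10⁻⁷),
sampled every 30–120 s. An energy audit integrates air enthalpy leaving to
the fan and latent heat removed alongside the state; the relative closure
residual is at machine precision on every default run and the suite
requires < 0.5 %. Threshold crossings (7/8th, half cooling times) use
linear interpolation between output samples; a 10× denser grid moves them
by < 0.5 %.

Two design choices deserve their own justification:

* **IPAS warm-stream bookkeeping.** The printed flow percentages make the
  22 % inter-package stream larger than the first zone's own 17.76 %
  throughput, so the stream cannot physically consist of first-zone outlet
  air alone. It is therefore drawn from package 1's zones in proportion to
  their throughput and arrives at the flow-weighted mix of their outlet
  temperatures; any other attribution leaves a percent-level hole in the
  energy budget.
* **Sub-inlet undercooling.** With the ambient vapor pressure evaluated at
  the zone temperature and a fixed 80 % RH, evaporation can cool fruit
  below the 1 °C dry-bulb toward the wet-bulb floor (minima near −2 °C
  late in a moisture-on run). The moisture-off sanity band (inlet − 0.5 °C)
  is therefore widened to inlet − 5 °C when transpiration is active. The
  optional `transported` humidity mode adds a vapor balance per zone, lets
  downstream air saturate, and accordingly removes less moisture.

## What the surrogate reproduces — and what it cannot

A hard bound frames the cooling-time results. At 0.4 L s⁻¹ kg⁻¹ the air
stream's enthalpy capacity is $\rho_a c_{p,a} \cdot 4\times10^{-4} =
0.52$ W K⁻¹ per kg of fruit against a fruit heat capacity of 3950 J kg⁻¹
K⁻¹. Any model in which outlet air is no warmer than the fruit it cools
therefore has a package time constant of at least 7596 s and a 7/8th
cooling time of at least $\tau \ln 8 \approx 263$ min. Published CFD
values for these layouts sit at or below that floor, so a conservative
surrogate cannot match them at face value. On top of the floor, the
well-mixed zone balance at per-zone NTU ≈ 2–3 yields an effective
conductance of $hA/(1+\mathrm{NTU})$ and lands moisture-off 7/8th times at
roughly 430–500 min, with the warm IPAS inter-package stream slowing
package 2 relative to package 1 (ΔT(3 h) ≈ 0.8 °C) and the two-zone
granularity smearing the MPAS dead-zone contrast (ΔT(3 h) ≈ 0.25 °C).
The transpiration results are not airflow-limited: the moisture-on 7/8th
time (~148 min) and the ARP-M1 package-1 time (~323 min) fall within 15 %
of their reference values. These numbers are exactly what
`scripts/acceptance.R` recomputes; none are asserted anywhere the code
does not derive them.

## The synthetic validation harness

The harness emulates an instrumented cooling run: eight probe fruits (two
per zone), center temperatures resampled at 60 s intervals, i.i.d.
Gaussian noise of 0.2 °C (K-thermocouple resolution class), three
replicates. The generator is bit-reproducible from `(config, seed)` and
restores the session RNG state. `goodness_of_fit` pools RMSE, R² and
maximum absolute error across probes and replicates;
`recover_skin_coefficient` refits $k_{g,skin}$ by golden-section search on
its logarithm against a moisture-on rerun of the simulator, flagging
estimates pinned at the search bounds. At 0.2 °C noise the median recovery
error over 20 seeds stays under 10 % and the mean under 3 %.

What passing these tests shows is internal consistency — the estimator is
unbiased and precise *when the model that generated the data is the model
being fitted*. It does not show that the surrogate captures real packages:
thermocouple lag, probe conduction error, fruit-to-fruit variability in
size and skin permeance, and within-zone airflow structure are all absent
from the generator.

## Worked example

```{r example, eval = FALSE}
design <- load_design("IPAS")
flow <- solve_flow_network(design, total_airflow(0.4, 2))
run_off <- simulate_cooling(design, flow,
                            config = simulation_config(duration = 36000,
                                                       out_interval = 60))
run_on <- simulate_cooling(design, flow,
                           config = simulation_config(duration = 36000,
                                                      out_interval = 60,
                                                      moisture = "on"))
cooling_summary(list(run_off, run_on))
```

Problem sizes used throughout (and in the test suite): 4 zones × 88 fruits
per package, 10 radial shells, 3–10 h simulated at 30–120 s output steps —
a deliberate desk-scale setting in which every headline quantity recomputes
in seconds.

## Known limitations

* No respiration heat, shrinkage, condensation or freezing (fruit can
  undercool below 0 °C in fixed-RH moisture-on runs; real fruit would
  freeze near −0.8 °C).
* Orifice mode ignores duct friction and momentum effects; it is a
  topology-exploration tool, not a CFD replacement.
* Two zones per package cannot resolve within-half heterogeneity; the
  reported fruit spread is a lower bound on the real spread.
* "Package-average" metrics use the mass-average fruit temperature by
  default; center-average variants are available and the probe harness
  intentionally uses center temperatures.
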