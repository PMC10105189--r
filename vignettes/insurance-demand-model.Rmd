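---
title: "A stock-flow model of private health insurance demand in a dual-track hospital system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-flow model of private health insurance demand in a dual-track hospital system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being modelled

Many universal health systems run a parallel private hospital sector.
People buy voluntary private health insurance chiefly to escape the
crowdedness of the public sector — but the private sector's capacity is
finite, so the more people hold insurance and use private care, the more
crowded the private sector becomes and the less attractive insurance
gets. That is a balancing feedback loop, and it implies an endogenous
ceiling on insurance penetration that a static, one-directional analysis
of public-sector waiting times cannot see.

`hidemand` implements this loop as a daily stock-flow simulator. It
ships with a Hong Kong 2009–2019 parameterization (a city where the
public sector provides roughly 88% of inpatient care and a
tax-incentivized voluntary insurance scheme launched on 2019-04-01),
but every quantity is an input, so the model transfers to any
dual-track system.

## Model structure

Let $HI_t$ be the fraction of the population holding individual private
health insurance and $I_t$ the total daily inpatient admission demand.
Insured patients use private care with probability $u$ (`use_hi`);
uninsured patients self-pay privately with probability $s$ (`selfpay`):

$$A^{pu}_t = I_t\,[HI_t(1-u) + (1-HI_t)(1-s)], \qquad
  A^{pr}_t = I_t - A^{pu}_t .$$

Patients accumulate in two hospital stocks with first-order discharge at
the sector length of stay ($L$ publicly, $\sigma L$ privately, where
$\sigma$ is the severity ratio `severity_ftr` — private hospitals treat
less severe cases with shorter stays):

$$\dot U^{pu} = A^{pu} - U^{pu}/L, \qquad
  \dot U^{pr} = A^{pr} - U^{pr}/(\sigma L).$$

Crowdedness is proxied by the bed-occupancy rate in its Little's-law
flow form (admissions × length of stay ÷ beds), which may exceed 1 to
represent over-capacity:

$$O^{pu}_t = A^{pu}_t L_t / B^{pu}_t, \qquad
  O^{pr}_t = A^{pr}_t L_t \sigma / B^{pr}_t .$$

The signed occupancy gap $G_t = O^{pu}_t - O^{pr}_t$ drives demand: its
excess over a structural baseline $G_0$ (`baseline_diff`), scaled by an
elasticity $\kappa$ (`occu_dmd`), feeds — after a third-order
exponential perception delay $D_3[\cdot]$ of total duration $\tau_D$
(one year by default) — into the penetration:

$$HI_t = HI_0 + D_3[(G_t - G_0)\,\kappa] + E^{tax}_t ,$$

clipped to $[0,1]$. The tax-incentive term activates at the policy start
date with an empty delay cascade:

$$E^{tax}_t = D_3\!\left[\frac{S}{\bar T}\,\lambda\right], \qquad
  S = C \cdot \rho \cdot r,$$

where $C$ is the deduction cap, $\rho$ the average premium ratio, $r$
the applicable tax-rate bracket, $\bar T$ the average tax paid per
capita and $\lambda$ the tax-demand elasticity (`tax_dmd`). With the
bundled Hong Kong policy, $S = 8000 \times 0.85 \times 0.06 = 408$ HKD,
about 14.2% of the average tax per capita.

Because the loop is balancing, a higher $HI$ shifts admissions to the
private sector, narrows the gap and damps further growth; the tax
incentive shifts the equilibrium but cannot escape the loop.

### Gap orientation

The demand effect must be positive when the *public* sector is the more
crowded one — that is what makes insurance attractive — so the gap
defaults to public-minus-private. The opposite sign convention is
available via `diff_orientation` for structural experiments; under it
the loop is reinforcing rather than balancing and the reported
monotonicities invert.

## Admission demand and the winter surge

Annual series (admission demand, length of stay, bed counts) are
interpreted as piecewise-constant step functions over their labelled
year. Most series follow an April–March fiscal-year convention; private
bed counts are labelled by natural year, as is common in the underlying
statistics. An optional mode interpolates linearly between year
midpoints.

Winter respiratory disease concentrates demand into a 90-day surge:
admissions ramp up linearly over the 30 days before January 15, hold at
`peak_ratio` (1.196) times the non-surge level through February 13, and
ramp back down over 30 days. The multiplier is evaluated pointwise per
day, so its annual sum equals the continuous trapezoid total
$(d-90)x + 30rx + 2\cdot 30\,(x+rx)/2$ minus an exact endpoint-sampling
correction of $(r-1)x$ — about 0.05% of the annual total, which the
test suite asserts as an identity. `nonsurge_from_annual()` inverts the
trapezoid formula in closed form when only annual totals are available.
Leap days count as non-surge days. The fiscal-year convention keeps each
winter inside a single input year, so no blending across year
boundaries is needed.

## Numerical choices

* **Integration** is explicit Euler at $dt = 1$ day (the native
  resolution of the demand profile), with optional substeps for
  convergence checks. Halving $dt$ moves the end-of-horizon penetration
  by well under one percentage point.
* **The third-order delay** is a cascade of three first-order stages
  with time constant $\tau_D/3$. With constant input the cascade is at
  an exact fixed point; its unit-step response at $t=\tau_D$ is within
  0.2% of the Erlang-3 closed form $1 - e^{-3}(1+3+9/2) \approx 0.5768$
  at $dt = 1$ over a 365-day duration (the suite cross-checks the
  cascade against an independent ODE solver).
* **Initialization**: stocks start empty and $HI$ at `baseline_hi`. The
  occupancy delay starts *matched* to its first input (each stage holds
  `input × duration/3`), the convention of common system-dynamics
  engines; a zero-history mode is available. The tax delay always
  starts with zero history at policy activation. Either way the first
  two simulated years show a warm-up transient — stocks fill, the delay
  chain loads — and analyses should discard them; this is why the
  bundled horizon starts six years before the evaluation window.
* **Degenerate inputs**: stocks are floored at zero, $HI$ is clipped to
  $[0,1]$, bed counts must be positive, and occupancies above 1 are
  deliberately representable.

## Parameters

| Parameter | Meaning | Unit | Bundled value |
|---|---|---|---|
| `use_hi` | insured patients using private care | fraction | 0.57 |
| `selfpay` | uninsured paying privately out of pocket | fraction | 0.06 |
| `severity_ftr` | private/public length-of-stay ratio | ratio | 0.39 (calibrated; 0.4 in the source statistics) |
| `occu_dmd` | gap-to-demand elasticity | 1/occupancy | 0.5 (calibrated; 2.22 × 0.6014 ≈ 1.3351 from literature) |
| `tax_dmd` | tax-saving-to-demand elasticity | — | 0.138 (= 0.036/0.26) |
| `baseline_hi` | penetration at horizon start | fraction | **must be supplied** |
| `baseline_diff` | structural occupancy-gap baseline | fraction | 0.055 |
| `delay_duration` | perception delay | days | 365 |
| `surge_peak_ratio` | winter peak multiplier | ratio | 1.196 |

`baseline_hi` comes from household-survey data that is not
redistributable with the package, so the bundle marks it as required.
The derivation helpers (`occu_dmd_literature()`, `tax_dmd_literature()`,
`avg_tax_per_capita()`) document how the literature-based priors were
assembled; calibration then replaced the occupancy elasticity by 0.5 and
the severity ratio by 0.39.

A structural calibration variant applies $\max(0,\cdot)$ to the
occupancy effect (`clamp_effect_nonneg`), preventing a crowded private
sector from pushing penetration *below* baseline; it is off by default
and enumerable during calibration.

One quantitative tension is worth recording: with the bundled
magnitudes the flow-form occupancy gap sits near 30 percentage points,
far above the 5.5-point structural baseline, so `baseline_diff` and
`baseline_hi` must be treated as joint calibration inputs rather than
independently measurable quantities.

## Calibration

Goodness of fit is the mean absolute percentage error (MAPE) between
the simulated penetration and dated survey observations, evaluated at
the exact survey dates (an option averages the simulated value over the
fieldwork year) inside an evaluation window — by convention the last
five simulated years, letting the warm-up transient die out.
`calibrate()` enumerates a user-supplied grid over the severity ratio,
the occupancy elasticity and the structural variant, and returns the
smallest-MAPE combination (first in grid order on ties) together with
the full table. The default grids (severity 0.35–0.43 by 0.01,
elasticity 0.1–1.4 by 0.05) bracket both the literature prior and the
calibrated optimum.

### Identifiability

The severity ratio and the occupancy elasticity are nearly collinear in
their effect on the penetration *level*: lowering $\sigma$ widens the
gap, which a smaller $\kappa$ can compensate. On a level-only reference
series the MAPE surface has a diagonal ridge of near-equivalent fits.
What separates the two parameters is the *time-variation* of the gap —
trend from differential capacity growth and the winter oscillation,
which $\kappa$ amplifies but $\sigma$ does not. The bundled
parameter-recovery study therefore uses a capacity-expansion scenario
(admissions +3%/yr, private beds +5%/yr against flat public capacity,
eight years, bimonthly surveys after a two-year warm-up); under it the
generating cell is recovered exactly without noise, and within one
neighboring grid cell in over 90% of replicates at 0.5-pp survey noise.
Users calibrating against a handful of near-stationary survey points
should expect only the ridge, not a point, to be identified — which is
also why exact reproduction of any single published (σ, κ) pair depends
on the grid and reference series used.

## Sensitivity analysis

`run_sensitivity()` draws each uncertain constant once per run —
Beta distributions for the $[0,1]$-bounded fractions, reconstructed
from a point estimate and a ±20% (or cited) range via
`beta_params_from_range()` (mean = point estimate, sd = range/4), and a
normal distribution for the unbounded elasticity — then summarizes 500
seeded runs as pointwise percentile envelopes (2.5/25/50/75/97.5) for
penetration, occupancies and admissions. Sampling is independent across
parameters (no correlation structure is asserted by the design);
Latin-hypercube stratification is available as an option. Because
random-number streams differ across simulation engines, reproduction of
published bands should be judged on the percentile envelopes, not on
individual runs. A robust qualitative result on the bundled inputs:
public-sector outputs vary much less across the band than
private-sector outputs, because the public sector is roughly five times
larger, so the same behavioural uncertainty moves it relatively little.

## The synthetic-scenario generator

`generate_scenario()` builds a complete synthetic system — annual
inputs with geometric growth, surge/non-surge admission pairs at the
exact configured peak ratio, and survey observations equal to the
simulated penetration plus additive Gaussian noise clipped to $[0,1]$ —
and is deterministic under its seed. It emulates the *statistical
shape* of real inputs: piecewise-annual series, a fixed-ratio seasonal
surge, sparse noisy surveys. It does **not** emulate demographic
structure, behavioural drift in `use_hi`/`selfpay`, reporting bias in
surveys, or demand shocks; a passing recovery study therefore shows
that the estimation machinery works when the model is true, not that
the model is true of any real system.

## Problem sizes

The bundled Hong Kong run is 3,927 daily steps (2009-04-01 to
2019-12-31) and completes in well under a second; the 500-run
sensitivity batch takes a few seconds. The recovery studies in the test
suite use 8-year scenarios with a 5 × 5 calibration grid and 50
replicates per noise level.

## Known limitations

* Inpatient bed occupancy is the only crowdedness proxy; outpatient
  waiting, imaging and surgery queues are outside the model.
* The insured/uninsured behavioural split is assumed identical between
  the general population and the hospitalized population.
* Discharge is first-order (exponential stay durations); no day-of-week
  or holiday effects; no stochastic demand noise.
* Disenrollment is only represented symmetrically through the effect
  term (or suppressed entirely under the clamp variant).
* `baseline_diff` is structural, not directly measurable from the
  printed occupancy equations (see the tension noted above).
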