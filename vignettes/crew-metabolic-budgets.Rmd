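---
title: "Modelling crew metabolic resource budgets with crewmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crew metabolic resource budgets with crewmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crewmet)
```

## Scope

crewmet estimates the life-support resources a spaceflight crew consumes as a
function of body size: total energy expenditure, oxygen uptake, carbon dioxide
output, metabolic heat rejected to the cabin, and hydration water. The model
is deterministic — given an anthropometric profile, an exercise prescription,
and a cabin environment, every downstream quantity follows from closed-form
physiology equations. Stochastic crew rosters are supported for sensitivity
studies, but randomness enters only through stature sampling.

The intended use is early life-support sizing: comparing candidate crews,
mission durations, and countermeasure-exercise policies, and quantifying how
much of the budget is attributable to body size versus exercise.

## Model chain

### Anthropometrics

Crew members are parameterised by stature alone; body mass follows from
geometric similarity at a fixed body-mass index,

$$m = \mathrm{BMI}\cdot s^2,$$

with BMI defaulting to 26.5 kg/m² and age to 40 y (a representative
mid-career male astronaut). Body surface area uses the Du Bois formula with
height in centimetres,

$$A_D = 0.007184\, h_{cm}^{0.725}\, m^{0.425},$$

and maximal aerobic power scales with mass at a relative
$\dot VO_{2\max}$ of 43.4 mL/kg/min.

### Resting metabolism

Resting metabolic rate uses the revised Harris–Benedict equation for males
(kcal/d, converted to MJ at 4.1868 kJ/kcal):

$$\mathrm{RMR} = 88.362 + 13.397\,m + 4.799\,h_{cm} - 5.677\,a.$$

Non-exercise daily energy is RMR scaled by a physical activity level
(PAL, default 1.4) plus a flat thermic effect of meals (206 kcal/d).
Resting gas exchange assumes 3.3 mL O₂/kg/min at a respiratory exchange
ratio of 0.788; 24-h resting gas volumes carry the same PAL multiplier.

### Exercise metabolism

The countermeasure prescription defaults to two 30-min bouts per day at 75%
of $\dot VO_{2\max}$, six days per week. Exercise energy expenditure comes
from the Weir equation with gas rates in L/min,

$$\mathrm{EE}\ (\mathrm{kcal/min}) = 3.94\,\dot VO_2 + 1.11\,\dot VCO_2,$$

at an exercising RER of 0.898. Excess post-exercise oxygen consumption is a
6% multiplier applied to bout energy, O₂, and CO₂ — but deliberately *not*
to heat or sweat, which are treated as within-bout steady-state quantities.

### Thermoregulation

Metabolic heat production converts oxygen uptake through the thermal
equivalent of oxygen (4.788 kcal/L at rest, 4.924 kcal/L during exercise).
Heat balance over the skin uses partitional calorimetry with a mean skin
temperature of 35 °C, 20% of exercising metabolic power exported as external
work, convective coefficient $h_c = 8.3 v^{0.6}$, linearised radiative
coefficient $h_r = 4.7$ W/m²/°C, clothing area factor 1.1, and a Lewis
relation of 16.5 °C/kPa. Saturation vapour pressure uses an Antoine
correlation. The steady-state sweat rate follows a linear regression on the
required and maximal evaporative heat fluxes,

$$\dot m_{sw}\ (\mathrm{g/m^2/h}) = 147 + 1.527\,E_{req} - 0.87\,E_{max},$$

floored at zero and scaled by surface area. These coefficients are standard
in the heat-strain literature; users can override every environmental
parameter through `cabin_environment()`.

A known property of the nominal cabin (22 °C, 55% RH, 0.5 m/s) is that the
required evaporation during intense exercise exceeds the evaporative
capacity ($E_{req}/E_{max} > 1$), i.e. full skin wettedness. The package
reports the ratio rather than clamping it, since the sweat regression was
fitted in that regime.

### Water requirements

Daily hydration water is the sum of insensible water needs, proportional to
energy turnover at 0.4 mL/kcal, and the urine volume needed to excrete the
dietary solute load at a target urine osmolality of 600 mOsm/kg. The solute
load is computed from protein (÷ 0.175 g/mmol) and twice the molar sodium
and potassium intakes. Exercise sweat volumes are added on exercise days.

Two energy bases for insensible water are available via `iwn_basis`:
`"weir_rest"` (default) derives energy turnover from Weir applied to the
PAL-scaled resting gas exchange plus the meal effect, which keeps the water
budget consistent with the gas budgets across the full stature range;
`"tee"` uses the Harris–Benedict total energy expenditure instead. The two
diverge by up to ~3% at the extremes of stature because Harris–Benedict and
mass-proportional gas exchange scale differently with height.

### Mission aggregation

`daily_budget()` composes a person-day; `mission_totals()` multiplies
person-days across a roster and duration, so crew- and mission-level totals
are exactly linear in crew size and days. By default exercise is budgeted
every day (a conservative sizing convention); `strict_schedule = TRUE`
instead credits only `days_per_week` exercise days per week.

The 24-h heat budget has a `heat_variant` switch. The default, `"basal"`,
applies the PAL multiplier to energy and gas volumes but leaves resting heat
production at its basal rate — matching the convention of published
life-support tables, where rejected heat is tied to basal oxidative
metabolism while activity energy is assumed to leave partly as external
work. `"consistent"` applies PAL to heat as well, making the 24-h first-law
closure exact.

## Synthetic crews

`roster_spec()` + `generate_roster()` draw crew statures from a fixed list,
a uniform band, or a truncated normal (inverse-CDF sampling, so draws are
reproducible across platforms from the stored seed). Statures outside the
1.495–1.905 m selection band used by flight agencies trigger a warning
rather than an error, since sensitivity studies legitimately probe the
edges. The generator preserves the caller's RNG state. Realism caveats: all
members share BMI, age, sex-specific equations, and relative aerobic
fitness, so roster variance reflects stature alone — adequate for sizing
studies, not for individual medical prediction.

## Numerical choices and limitations

* All computations are closed-form; no iteration or integration error.
  Totals are exact sums of per-day quantities, so linearity identities hold
  to machine precision and are tested as such.
* Energy units are MJ internally; kcal appears only at the equation
  interfaces (4.1868 kJ/kcal). Heat power is W; the kcal/min→W conversion
  uses 60/4186.8.
* The sweat regression predicts roughly 8–9% lower rates than some published
  exercise tables for the same environment; the discrepancy is systematic
  (it cancels in size *contrasts*) and is within the scatter of the original
  regression.
* The model is male-only and steady-state: no menstrual, microgravity
  fluid-shift, deconditioning, or transient thermal effects.
* Harris–Benedict RMR and mass-proportional heat production diverge with
  stature (≈6% at 1.90 m), so cross-checks between the energy and heat
  budgets should be made near the anthropometric centre of the range.

## Worked example

```{r example}
member <- crew_member(stature = 1.70)
member

day <- daily_budget(member, exercise_prescription())
unlist(day[c("tee", "o2", "co2", "heat", "water")])

roster <- generate_roster(roster_spec(4, sampler = "truncnorm", seed = 7))
mission <- mission_scenario(roster, duration = 180,
                            prescription = exercise_prescription())
mission_totals(mission)
```

Batch studies run through a YAML configuration and `run_pipeline()`, or the
`inst/cli/crewmet` command-line front end, which write the characteristic,
bout, daily, and contrast tables with an embedded configuration hash for
provenance.
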