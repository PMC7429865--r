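# crewmet

Metabolic resource budgets for spaceflight crews.

Life-support systems are sized against what a crew consumes and produces:
food energy, oxygen, carbon dioxide, metabolic heat that the thermal control
loop must reject, and potable water. All of these scale with astronaut body
size and with the daily countermeasure exercise that keeps crews healthy in
microgravity. crewmet provides a deterministic, closed-form model of these
budgets so that mission designers can compare candidate crew anthropometries,
exercise policies, and mission durations, and can attribute resource deltas
to body size versus exercise.

## Model

A crew member is parameterised by stature *s*; mass follows geometric
similarity at fixed BMI, and surface area follows Du Bois:

```
m   = BMI · s²                       (BMI = 26.5 kg/m² default)
A_D = 0.007184 · h_cm^0.725 · m^0.425
```

Resting metabolic rate uses the revised Harris–Benedict equation for males;
daily energy is `PAL · RMR + TEM` (PAL = 1.4, thermic effect of meals
206 kcal/d). Exercise energy comes from the Weir equation on the prescribed
fraction of VO₂max (default two 30-min bouts at 75%), with a 6% excess
post-exercise oxygen consumption applied to energy and gas volumes:

```
EE (kcal/min) = 3.94 · V̇O₂ + 1.11 · V̇CO₂      (gas rates in L/min)
```

Metabolic heat production converts oxygen uptake through its thermal
equivalent; heat balance across the skin uses partitional calorimetry
(convection, radiation, clothing resistances) and a linear steady-state
sweat-rate prediction from the required and maximal evaporative fluxes.
Hydration water is insensible water (0.4 mL/kcal of energy turnover) plus
the urine volume required to excrete the dietary solute load at
600 mOsm/kg. Person-days aggregate linearly to crew- and mission-level
totals. See the vignette (`vignettes/crew-metabolic-budgets.Rmd`) for the
full equation chain, parameter rationale, and limitations.

## Example

```r
library(crewmet)

member <- crew_member(stature = 1.70)
member
#> <crew_member> stature 1.70 m, age 40 y, BMI 26.5 kg/m^2
#>   body mass 76.6 kg, BSA 1.88 m^2, VO2max 3.32 L/min

day <- daily_budget(member, exercise_prescription())
unlist(day[c("tee", "o2", "co2", "heat", "water")])
#>        tee         o2        co2       heat      water
#>  14.122370 668.049423 543.862866  10.379586   3.589867
# MJ, L, L, MJ, L per person-day

roster  <- generate_roster(roster_spec(4, sampler = "truncnorm", seed = 7))
mission <- mission_scenario(roster, duration = 180,
                            prescription = exercise_prescription())
mission_totals(mission)
#> <mission_totals> 4 crew x 180 d: energy 10073 MJ, O2 475910 L,
#>   CO2 387441 L, heat 7394.3 MJ, water 2571 L
```

Batch studies run from a YAML configuration through `run_pipeline()` or the
command-line front end installed at `inst/cli/crewmet`, which emit the
characteristic, exercise-bout, daily-budget, and contrast tables as CSV with
an embedded configuration hash.

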