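## Physical and physiological constants used throughout the package.
## All internal computation is unrounded; report renderers round to table
## precision at the last moment.

# Thermochemical calorie-based conversion used by dietetics tables.
KCAL_TO_KJ <- 4.1868

# kcal/min -> J/s.  60 / 4186.8 = 0.01433 (as conventionally quoted).
KCAL_MIN_PER_WATT <- 0.01433

# Thermal equivalent of 1 L O2 (kcal) at the fixed resting and exercising
# respiratory exchange ratios adopted by the model (RER 0.788 and 0.898).
THERMAL_EQUIV_REST_KCAL_PER_L <- 4.788
THERMAL_EQUIV_EXERCISE_KCAL_PER_L <- 4.924

# Weir indirect-calorimetry coefficients, kcal/min with gas rates in L/min.
WEIR_O2 <- 3.94
WEIR_CO2 <- 1.11

# Urine concentrating target (mmol/kg) for the renal water requirement.
URINE_OSMOLALITY <- 600

# Space-agency stature selection band (m); rosters outside it warn.
AGENCY_STATURE_BAND <- c(1.495, 1.905)

MIN_PER_DAY <- 1440
SEC_PER_DAY <- 86400

## Default crew physiology (all-male reference population): age 40 y,
## BMI 26.5 kg/m^2, relative VO2max 43.4 mL/kg/min, resting VO2
## 3.3 mL/kg/min, RER 0.788 at rest and 0.898 at 75% VO2max.
DEFAULT_AGE <- 40
DEFAULT_BMI <- 26.5
DEFAULT_VO2MAX_REL <- 43.4
DEFAULT_VO2_REST_REL <- 3.3
DEFAULT_RER_REST <- 0.788
DEFAULT_RER_EXERCISE <- 0.898

## Default daily-energy components: physical activity level 1.4 (sedentary
## confinement), thermic effect of meals 206 kcal/d (three meals).
DEFAULT_PAL <- 1.4
DEFAULT_TEM_KCAL <- 206

## Default dietary intakes (ISS expedition food-log means).
DEFAULT_PROTEIN_G <- 95
DEFAULT_SODIUM_MG <- 4320
DEFAULT_POTASSIUM_MG <- 3062

## Reference stature grid (m) and mission durations (d) for report tables.
REFERENCE_STATURES <- c(1.50, 1.60, 1.70, 1.80, 1.90)
REFERENCE_DURATIONS <- c(30, 90, 180, 360, 720, 1080)
REFERENCE_CREW_SIZE <- 4

# internal: domain-error helper naming the offending argument
stop_domain <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(field, "must be a positive finite number")
  }
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_domain(field, "must be a non-negative finite number")
  }
  invisible(x)
}
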