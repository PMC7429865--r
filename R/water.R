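#' Insensible water needs from daily energy turnover
#'
#' \deqn{IWN (L/d) = 0.4 \times EnergyNeeds_{kcal} / 1000}
#' Respiratory water losses are taken as balanced by metabolic water
#' production and are not added.
#'
#' @param energy_needs Daily energy needs, kcal/d.
#' @return Insensible water needs, L/d.
#' @export
insensible_water <- function(energy_needs) {
  check_nonnegative(energy_needs, "energy_needs")
  0.4 * energy_needs / 1000
}

#' Dietary solute load
#'
#' Renal solute load from protein (urea) and the two major electrolytes:
#' \deqn{DSL (mmol/d) = Protein/0.175 + 2 (Na/23 + K/39)}
#' with protein in g/d and sodium/potassium in mg/d.  Defaults are the ISS
#' expedition food-log intakes (95 g/d protein, 4,320 mg/d Na, 3,062 mg/d K).
#'
#' @param protein Protein intake, g/d.
#' @param sodium Sodium intake, mg/d.
#' @param potassium Potassium intake, mg/d.
#' @return Dietary solute load, mmol/d.
#' @export
dietary_solute_load <- function(protein = DEFAULT_PROTEIN_G,
                                sodium = DEFAULT_SODIUM_MG,
                                potassium = DEFAULT_POTASSIUM_MG) {
  check_nonnegative(protein, "protein")
  check_nonnegative(sodium, "sodium")
  check_nonnegative(potassium, "potassium")
  protein / 0.175 + 2 * (sodium / 23 + potassium / 39)
}

#' Urine volume to excrete a solute load at 600 mmol/kg
#'
#' @param dsl Dietary solute load, mmol/d.
#' @return Obligatory urine volume, L/d.
#' @export
uv600 <- function(dsl) {
  check_nonnegative(dsl, "dsl")
  dsl / URINE_OSMOLALITY
}

#' Assemble a daily water budget
#'
#' Basal water is insensible losses plus obligatory urine volume; exercise
#' sweat replacement is added on top.  Transcutaneous loss carries no
#' explicit term (it enters total body-water balance only), which is the
#' likely source of a residual of order 0.1 L/d against reference budgets.
#'
#' @param iwn Insensible water needs, L/d.
#' @param uv600 Obligatory urine volume, L/d.
#' @param exercise_sweat Sweat to replace, L/d.
#' @return An object of class `water_budget`: `iwn`, `uv600`, `basal_water`,
#'   `exercise_sweat`, `total_water`, all L/d.
#' @export
daily_water <- function(iwn, uv600, exercise_sweat = 0) {
  check_nonnegative(iwn, "iwn")
  check_nonnegative(uv600, "uv600")
  check_nonnegative(exercise_sweat, "exercise_sweat")
  basal <- iwn + uv600
  structure(
    list(
      iwn = iwn,
      uv600 = uv600,
      basal_water = basal,
      exercise_sweat = exercise_sweat,
      total_water = basal + exercise_sweat
    ),
    class = "water_budget"
  )
}

#' @export
print.water_budget <- function(x, ...) {
  cat(sprintf(
    "<water_budget> IWN %.2f + UV600 %.2f = basal %.2f L/d; sweat %.2f; total %.2f L/d\n",
    x$iwn, x$uv600, x$basal_water, x$exercise_sweat, x$total_water
  ))
  invisible(x)
}

#' Daily energy needs for the insensible-water calculation
#'
#' Two selectable definitions of the "energy needs" driving insensible
#' water loss:
#' \describe{
#'   \item{`"weir_rest"` (default)}{Weir-equation energy of resting gas
#'     exchange scaled by the physical activity level, plus the thermic
#'     effect of meals.  Being proportional to body mass (plus the fixed
#'     TEM), this reproduces reference basal-fluid budgets across the
#'     stature range within 1\%.}
#'   \item{`"tee"`}{The scenario's full 24-h total energy expenditure,
#'     including exercise energy when prescribed.}
#' }
#'
#' @param member A [crew_member()].
#' @param profile A [resting_profile()] for the member.
#' @param basis `"weir_rest"` or `"tee"`.
#' @param exercise_energy_mj Daily exercise energy (MJ/d) counted only under
#'   the `"tee"` basis.
#' @return Energy needs in kcal/d.
#' @export
iwn_energy_needs <- function(member, profile,
                             basis = c("weir_rest", "tee"),
                             exercise_energy_mj = 0) {
  basis <- match.arg(basis)
  tem_kcal <- profile$tem * 1000 / KCAL_TO_KJ
  if (basis == "weir_rest") {
    weir_kcal_min <- WEIR_O2 * profile$vo2_rest + WEIR_CO2 * profile$vco2_rest
    weir_kcal_min * MIN_PER_DAY * profile$pal + tem_kcal
  } else {
    tee_mj <- profile$rmr * profile$pal + profile$tem + exercise_energy_mj
    tee_mj * 1000 / KCAL_TO_KJ
  }
}

#' Water budget for one crew member's day
#'
#' Convenience wrapper: computes the basal water budget for a member from
#' the selected energy basis and constant dietary intakes, adding exercise
#' sweat when supplied.
#'
#' @inheritParams iwn_energy_needs
#' @param exercise_sweat_l Sweat losses to replace, L/d.
#' @param protein,sodium,potassium Daily intakes (g/d, mg/d, mg/d).
#' @return A [daily_water()] budget.
#' @export
water_budget <- function(member, profile,
                         exercise_sweat_l = 0,
                         basis = c("weir_rest", "tee"),
                         exercise_energy_mj = 0,
                         protein = DEFAULT_PROTEIN_G,
                         sodium = DEFAULT_SODIUM_MG,
                         potassium = DEFAULT_POTASSIUM_MG) {
  basis <- match.arg(basis)
  kcal <- iwn_energy_needs(member, profile, basis, exercise_energy_mj)
  daily_water(
    iwn = insensible_water(kcal),
    uv600 = uv600(dietary_solute_load(protein, sodium, potassium)),
    exercise_sweat = exercise_sweat_l
  )
}
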