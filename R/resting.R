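#' Resting metabolic rate (revised Harris-Benedict, males)
#'
#' \deqn{RMR_{kcal/d} = 88.362 + 13.397 M + 4.799 H_{cm} - 5.677 A}
#' with mass \eqn{M} in kg, height in cm and age \eqn{A} in years, converted
#' to MJ/d at 4.1868 kJ/kcal.
#'
#' @param body_mass Body mass, kg.
#' @param stature Standing height, m.
#' @param age Age, years (0, 120).
#' @return Resting metabolic rate in MJ/d.
#' @examples
#' rmr_harris_benedict(76.585, 1.70, 40)  # ~7.13 MJ/d
#' @export
rmr_harris_benedict <- function(body_mass, stature, age) {
  check_positive(body_mass, "body_mass")
  check_positive(stature, "stature")
  if (!is.numeric(age) || any(age <= 0) || any(age >= 120)) {
    stop_domain("age", "must lie strictly between 0 and 120 years")
  }
  kcal <- 88.362 + 13.397 * body_mass + 4.799 * (stature * 100) - 5.677 * age
  kcal * KCAL_TO_KJ / 1000
}

#' Non-exercise activity thermogenesis from a physical activity level
#'
#' NEAT is the habitual-activity energy above resting metabolism,
#' \eqn{(PAL - 1) \times RMR}.  PAL 1.4 corresponds to a very sedentary,
#' confined lifestyle.
#'
#' @param rmr Resting metabolic rate, MJ/d.
#' @param pal Physical activity level (>= 1).
#' @return NEAT in MJ/d.
#' @export
neat_from_pal <- function(rmr, pal) {
  check_positive(rmr, "rmr")
  if (!is.numeric(pal) || any(pal < 1)) {
    stop_domain("pal", "must be >= 1")
  }
  (pal - 1) * rmr
}

#' Resting gas exchange
#'
#' Absolute resting oxygen consumption from the mass-relative value, and
#' carbon dioxide production via the resting respiratory exchange ratio.
#'
#' @param body_mass Body mass, kg.
#' @param vo2_rest_rel Resting VO2, mL/kg/min.
#' @param rer_rest Resting respiratory exchange ratio.
#' @return A list with `vo2` and `vco2`, both L/min.
#' @examples
#' resting_gas_exchange(76.585, 3.3, 0.788)
#' @export
resting_gas_exchange <- function(body_mass, vo2_rest_rel, rer_rest) {
  check_positive(body_mass, "body_mass")
  check_positive(vo2_rest_rel, "vo2_rest_rel")
  check_positive(rer_rest, "rer_rest")
  vo2 <- body_mass * vo2_rest_rel / 1000
  list(vo2 = vo2, vco2 = rer_rest * vo2)
}

#' Metabolic heat production from oxygen uptake
#'
#' Converts an oxygen uptake to heat production using the thermal equivalent
#' of oxygen at the prevailing RER:
#' \deqn{M_{prod} (J/s) = VO_2 (L/min) \times TE (kcal/L) / 0.01433}
#' where 0.01433 = 60/4186.8 converts kcal/min to watts.  The thermal
#' equivalents used by the model are 4.788 kcal/L at the resting RER (0.788)
#' and 4.924 kcal/L at the exercising RER (0.898).
#'
#' @param vo2 Oxygen uptake, L/min.
#' @param thermal_equiv Thermal equivalent of oxygen, kcal per litre O2.
#' @return Heat production in J/s (W).
#' @examples
#' mprod(0.2527, 4.788)  # ~84.4 J/s
#' @export
mprod <- function(vo2, thermal_equiv) {
  check_nonnegative(vo2, "vo2")
  check_positive(thermal_equiv, "thermal_equiv")
  vo2 * thermal_equiv / KCAL_MIN_PER_WATT
}

#' Resting metabolic profile of a crew member
#'
#' Assembles the resting-side quantities for one crew member: RMR
#' (Harris-Benedict), NEAT from the physical activity level, the fixed
#' thermic effect of meals, resting gas exchange and basal heat production.
#'
#' @param member A [crew_member()].
#' @param pal Physical activity level (default 1.4).
#' @param tem_kcal Thermic effect of meals, kcal/d (default 206).
#' @return An object of class `resting_profile`: list with `rmr`, `neat`,
#'   `tem` (MJ/d), `pal`, `vo2_rest`, `vco2_rest` (L/min) and `mprod_basal`
#'   (J/s).
#' @examples
#' resting_profile(crew_member(1.70))
#' @export
resting_profile <- function(member, pal = DEFAULT_PAL, tem_kcal = DEFAULT_TEM_KCAL) {
  stopifnot(is_crew_member(member))
  rmr <- rmr_harris_benedict(member$body_mass, member$stature, member$age)
  gas <- resting_gas_exchange(member$body_mass, member$vo2_rest_rel, member$rer_rest)
  structure(
    list(
      rmr = rmr,
      neat = neat_from_pal(rmr, pal),
      tem = tem_kcal * KCAL_TO_KJ / 1000,
      pal = pal,
      vo2_rest = gas$vo2,
      vco2_rest = gas$vco2,
      mprod_basal = mprod(gas$vo2, THERMAL_EQUIV_REST_KCAL_PER_L)
    ),
    class = "resting_profile"
  )
}

#' @export
print.resting_profile <- function(x, ...) {
  cat(sprintf(
    "<resting_profile> RMR %.2f MJ/d, NEAT %.2f MJ/d (PAL %.2f), TEM %.2f MJ/d\n",
    x$rmr, x$neat, x$pal, x$tem
  ))
  cat(sprintf(
    "  VO2 %.3f L/min, VCO2 %.3f L/min, basal Mprod %.1f J/s\n",
    x$vo2_rest, x$vco2_rest, x$mprod_basal
  ))
  invisible(x)
}
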