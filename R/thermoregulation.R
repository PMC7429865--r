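#' Cabin thermal environment and clothing biophysics
#'
#' Describes the vehicle atmosphere and the biophysical coefficients used by
#' the partitional-calorimetry heat balance.  Defaults are the ISS-like
#' cabin: 22 degC, 55\% relative humidity, 760 mmHg, 0.5 m/s fan-driven air
#' speed, core temperature 37 degC, and light sports clothing with thermal
#' resistance 0.06 m^2.degC/W and evaporative resistance 0.01 m^2.kPa/W.
#'
#' Mean skin temperature during exercise is not an input the model takes
#' from measurements; the conventional exercising value of 35 degC is the
#' default and is exposed here.  The transfer-coefficient choices (all
#' exposed): convective coefficient \eqn{h_c = 8.3 v^{0.6}} W/m^2/degC
#' (forced convection), radiative coefficient 4.7 W/m^2/degC, clothing area
#' factor 1.1, Lewis relation 16.5 degC/kPa for the evaporative boundary
#' layer.
#'
#' @param air_temp Air (and mean radiant) temperature, degC.
#' @param relative_humidity Fractional relative humidity in (0, 1].
#' @param barometric_pressure Cabin pressure, mmHg.
#' @param air_velocity Air speed over the skin, m/s.
#' @param core_temp Core temperature, degC.
#' @param skin_temp Mean skin temperature, degC (must be below core).
#' @param clothing_thermal_resistance Intrinsic clothing thermal resistance,
#'   m^2.degC/W.
#' @param clothing_evaporative_resistance Intrinsic clothing evaporative
#'   resistance, m^2.kPa/W.
#' @param hc_coef,hc_exp Forced-convection correlation h_c = hc_coef * v^hc_exp.
#' @param hr Linearised radiative heat-transfer coefficient, W/m^2/degC.
#' @param fcl Clothing area factor (clothed/nude surface ratio).
#' @param lewis Lewis relation, degC/kPa.
#' @return An object of class `cabin_environment`.
#' @export
cabin_environment <- function(air_temp = 22,
                              relative_humidity = 0.55,
                              barometric_pressure = 760,
                              air_velocity = 0.5,
                              core_temp = 37,
                              skin_temp = 35,
                              clothing_thermal_resistance = 0.06,
                              clothing_evaporative_resistance = 0.01,
                              hc_coef = 8.3,
                              hc_exp = 0.6,
                              hr = 4.7,
                              fcl = 1.1,
                              lewis = 16.5) {
  if (relative_humidity <= 0 || relative_humidity > 1) {
    stop_domain("relative_humidity", "must lie in (0, 1]")
  }
  check_nonnegative(air_velocity, "air_velocity")
  if (skin_temp >= core_temp) {
    stop_domain("skin_temp", "must be below core_temp")
  }
  structure(
    list(
      air_temp = air_temp,
      relative_humidity = relative_humidity,
      barometric_pressure = barometric_pressure,
      air_velocity = air_velocity,
      core_temp = core_temp,
      skin_temp = skin_temp,
      clothing_thermal_resistance = clothing_thermal_resistance,
      clothing_evaporative_resistance = clothing_evaporative_resistance,
      hc_coef = hc_coef,
      hc_exp = hc_exp,
      hr = hr,
      fcl = fcl,
      lewis = lewis
    ),
    class = "cabin_environment"
  )
}

#' @export
print.cabin_environment <- function(x, ...) {
  cat(sprintf(
    "<cabin_environment> %.1f degC, %.0f%% RH, %.2f m/s, skin %.1f degC, Icl %.3f, Re,cl %.3f\n",
    x$air_temp, 100 * x$relative_humidity, x$air_velocity, x$skin_temp,
    x$clothing_thermal_resistance, x$clothing_evaporative_resistance
  ))
  invisible(x)
}

#' Saturation vapour pressure of water (Antoine form)
#'
#' Antoine equation for water over 0--45 degC:
#' \deqn{\log_{10} P_{mmHg} = 8.07131 - 1730.63 / (233.426 + T)}
#' converted to kPa (1 mmHg = 0.133322 kPa).
#'
#' @param temp_c Temperature in degC.
#' @return Saturation vapour pressure in kPa.
#' @export
saturation_vapour_pressure <- function(temp_c) {
  p_mmhg <- 10^(8.07131 - 1730.63 / (233.426 + temp_c))
  p_mmhg * 0.133322
}

# internal: convective coefficient at the environment's air speed
convective_coefficient <- function(env) {
  env$hc_coef * env$air_velocity^env$hc_exp
}

#' Net metabolic heat per unit surface area
#'
#' Metabolic heat production less the fraction converted to external
#' mechanical work (20\% of Mprod for non-cyclist cycle ergometry),
#' normalised to body surface area.
#'
#' @param mprod Metabolic heat production, J/s.
#' @param external_work_fraction Fraction of Mprod exported as work, [0, 1).
#' @param bsa Body surface area, m^2.
#' @return Net metabolic heat, W/m^2.
#' @export
net_metabolic_heat <- function(mprod, external_work_fraction = 0.2, bsa) {
  check_nonnegative(mprod, "mprod")
  if (external_work_fraction < 0 || external_work_fraction >= 1) {
    stop_domain("external_work_fraction", "must lie in [0, 1)")
  }
  check_positive(bsa, "bsa")
  mprod * (1 - external_work_fraction) / bsa
}

#' Dry (convective + radiative) heat loss through clothing
#'
#' Resistance-network form: the skin-to-operative-temperature gradient over
#' the sum of the intrinsic clothing resistance and the boundary air-layer
#' resistance \eqn{1 / ((h_c + h_r) f_{cl})}.  With the mean radiant
#' temperature taken equal to air temperature, the operative temperature is
#' the air temperature.  A hot environment (air above skin) returns a
#' negative value (dry heat gain) rather than an error.
#'
#' @param env A [cabin_environment()].
#' @return Dry heat loss in W/m^2 (positive = loss from the body).
#' @export
dry_heat_loss <- function(env) {
  stopifnot(inherits(env, "cabin_environment"))
  h <- convective_coefficient(env) + env$hr
  r_air <- 1 / (h * env$fcl)
  r_total <- env$clothing_thermal_resistance + r_air
  (env$skin_temp - env$air_temp) / r_total
}

#' Maximal evaporative capacity of the environment
#'
#' The skin-saturation to ambient vapour-pressure gradient over the total
#' evaporative resistance: intrinsic clothing evaporative resistance plus
#' the boundary-layer term \eqn{1 / (L h_c f_{cl})} from the Lewis relation.
#'
#' @param env A [cabin_environment()].
#' @return Emax in W/m^2.
#' @export
emax <- function(env) {
  stopifnot(inherits(env, "cabin_environment"))
  p_skin <- saturation_vapour_pressure(env$skin_temp)
  p_air <- env$relative_humidity * saturation_vapour_pressure(env$air_temp)
  he <- env$lewis * convective_coefficient(env)
  re_air <- 1 / (he * env$fcl)
  re_total <- env$clothing_evaporative_resistance + re_air
  (p_skin - p_air) / re_total
}

#' Steady-state exercise sweat rate
#'
#' Empirical prediction of steady-state whole-body sweating from the
#' required evaporative cooling and the evaporative capacity of the
#' environment:
#' \deqn{\dot m_{sw} (g\,m^{-2}h^{-1}) = 147 + 1.527\,E_{req} - 0.87\,E_{max}}
#' scaled by body surface area and converted to mL/min (1 g of sweat taken
#' as 1 mL).  No allowance is made for the thermal inertial lag in sweating
#' onset.  The prediction is floored at zero.
#'
#' @param ereq Required evaporative cooling, W/m^2.
#' @param emax Maximal evaporative capacity, W/m^2 (must be positive:
#'   an uncompensable environment is outside the model's scope).
#' @param bsa Body surface area, m^2.
#' @return Whole-body sweat rate, mL/min.
#' @export
sweat_rate <- function(ereq, emax, bsa) {
  if (!is.numeric(emax) || any(emax <= 0)) {
    stop_domain("emax", "must be positive (uncompensable environment out of scope)")
  }
  check_positive(bsa, "bsa")
  msw <- 147 + 1.527 * ereq - 0.87 * emax # g/m^2/h
  pmax(msw, 0) * bsa / 60
}

#' Partitional-calorimetry heat balance during exercise
#'
#' Runs the full heat-balance chain for one crew member exercising in a
#' cabin environment: net metabolic heat (after external work), dry heat
#' exchange, required evaporative cooling \eqn{E_{req} = M_{net} - dry},
#' maximal evaporative capacity \eqn{E_{max}}, and the predicted whole-body
#' sweat rate.
#'
#' @param member A [crew_member()].
#' @param env A [cabin_environment()].
#' @param intensity_fraction Exercise intensity as a fraction of VO2max.
#' @param external_work_fraction Fraction of Mprod exported as mechanical work.
#' @return An object of class `heat_balance`: `mnet`, `dry_loss`, `ereq`,
#'   `emax` (W/m^2), `wettedness` (Ereq/Emax) and `sweat_rate` (mL/min,
#'   whole body).
#' @examples
#' heat_balance(crew_member(1.70), cabin_environment())
#' @export
heat_balance <- function(member, env = cabin_environment(),
                         intensity_fraction = 0.75,
                         external_work_fraction = 0.2) {
  stopifnot(is_crew_member(member))
  rates <- exercise_rates(member, intensity_fraction)
  mnet <- net_metabolic_heat(rates$mprod, external_work_fraction, member$bsa)
  dry <- dry_heat_loss(env)
  ereq <- mnet - dry
  em <- emax(env)
  structure(
    list(
      mnet = mnet,
      dry_loss = dry,
      ereq = ereq,
      emax = em,
      wettedness = ereq / em,
      sweat_rate = sweat_rate(ereq, em, member$bsa)
    ),
    class = "heat_balance"
  )
}

#' @export
print.heat_balance <- function(x, ...) {
  cat(sprintf(
    "<heat_balance> Mnet %.1f, dry %.1f, Ereq %.1f, Emax %.1f W/m^2; w %.2f; SR %.1f mL/min\n",
    x$mnet, x$dry_loss, x$ereq, x$emax, x$wettedness, x$sweat_rate
  ))
  invisible(x)
}
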