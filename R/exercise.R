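#' Countermeasure exercise prescription
#'
#' Describes the in-flight aerobic countermeasure schedule.  The reference
#' prescription is two 30-min steady-state bouts per day at 75\% VO2max,
#' 6 d/week, with excess post-exercise oxygen consumption (EPOC) equal to 6\%
#' of the in-bout consumption.  Warm-up and cool-down are excluded;
#' resistance exercise is represented as the second identical aerobic bout.
#'
#' @param intensity_fraction Fraction of VO2max, in (0, 1].
#' @param bout_duration Bout length, minutes.
#' @param bouts_per_day Number of bouts per exercise day.
#' @param days_per_week Exercise days per week, 1--7.
#' @param epoc_fraction EPOC as a fraction of in-bout O2/CO2/energy, in [0, 1).
#' @return An object of class `exercise_prescription`.
#' @export
exercise_prescription <- function(intensity_fraction = 0.75,
                                  bout_duration = 30,
                                  bouts_per_day = 2,
                                  days_per_week = 6,
                                  epoc_fraction = 0.06) {
  if (intensity_fraction <= 0 || intensity_fraction > 1) {
    stop_domain("intensity_fraction", "supramaximal not modelled; need 0 < fraction <= 1")
  }
  check_nonnegative(bout_duration, "bout_duration")
  if (bouts_per_day < 0 || bouts_per_day != round(bouts_per_day)) {
    stop_domain("bouts_per_day", "must be a non-negative integer")
  }
  if (days_per_week < 1 || days_per_week > 7) {
    stop_domain("days_per_week", "must lie in 1..7")
  }
  if (epoc_fraction < 0 || epoc_fraction >= 1) {
    stop_domain("epoc_fraction", "must lie in [0, 1)")
  }
  structure(
    list(
      intensity_fraction = intensity_fraction,
      bout_duration = bout_duration,
      bouts_per_day = bouts_per_day,
      days_per_week = days_per_week,
      epoc_fraction = epoc_fraction
    ),
    class = "exercise_prescription"
  )
}

#' @export
print.exercise_prescription <- function(x, ...) {
  cat(sprintf(
    "<exercise_prescription> %d x %g min at %.0f%% VO2max, %d d/week, EPOC %.0f%%\n",
    x$bouts_per_day, x$bout_duration, 100 * x$intensity_fraction,
    x$days_per_week, 100 * x$epoc_fraction
  ))
  invisible(x)
}

#' Steady-state exercise gas exchange, energy expenditure and heat production
#'
#' Exercise VO2 is the prescribed fraction of absolute VO2max; VCO2 follows
#' from the exercising RER.  Energy expenditure uses the Weir equation,
#' \deqn{EE (kcal/min) = 3.94\,VO_2 + 1.11\,VCO_2} with gas rates in L/min
#' (the formula is often printed with mL/min, but only the L/min reading
#' gives kcal/min).  Heat production uses [mprod()] with the exercising
#' thermal equivalent of oxygen (4.924 kcal/L at RER 0.898).
#'
#' @param member A [crew_member()].
#' @param intensity_fraction Fraction of VO2max, in (0, 1].
#' @return A list of steady-state rates: `vo2`, `vco2` (L/min), `ee`
#'   (kcal/min), `mprod` (J/s).
#' @examples
#' exercise_rates(crew_member(1.70), 0.75)
#' @export
exercise_rates <- function(member, intensity_fraction = 0.75) {
  stopifnot(is_crew_member(member))
  if (!is.numeric(intensity_fraction) || intensity_fraction <= 0) {
    stop_domain("intensity_fraction", "must be positive")
  }
  if (intensity_fraction > 1) {
    stop_domain("intensity_fraction", "supramaximal not modelled")
  }
  vo2 <- intensity_fraction * member$vo2max_abs
  vco2 <- member$rer_exercise * vo2
  list(
    vo2 = vo2,
    vco2 = vco2,
    ee = WEIR_O2 * vo2 + WEIR_CO2 * vco2,
    mprod = mprod(vo2, THERMAL_EQUIV_EXERCISE_KCAL_PER_L)
  )
}

#' Totals for a single exercise bout
#'
#' Integrates steady-state rates over one bout.  Energy, O2 and CO2 carry
#' the EPOC multiplier (1 + epoc_fraction); heat and sweat do not (EPOC heat
#' is dissipated over recovery and sweat prediction is steady-state during
#' the bout only).
#'
#' @param rates Steady-state rates from [exercise_rates()].
#' @param bout_duration Bout length, minutes.
#' @param epoc_fraction EPOC fraction of in-bout O2/CO2/energy.
#' @param sweat_rate Whole-body sweat rate during the bout, mL/min.
#' @return An object of class `bout_totals`: `energy` (MJ), `o2`, `co2` (L),
#'   `heat` (kJ), `sweat` (mL).
#' @examples
#' r <- exercise_rates(crew_member(1.70), 0.75)
#' bout_totals(r, 30, 0.06, 13.4)
#' @export
bout_totals <- function(rates, bout_duration = 30, epoc_fraction = 0.06,
                        sweat_rate = 0) {
  stopifnot(is.list(rates), all(c("vo2", "vco2", "ee", "mprod") %in% names(rates)))
  if (!is.numeric(bout_duration) || bout_duration < 0) {
    stop_domain("bout_duration", "must be non-negative")
  }
  if (epoc_fraction < 0 || epoc_fraction >= 1) {
    stop_domain("epoc_fraction", "must lie in [0, 1)")
  }
  check_nonnegative(sweat_rate, "sweat_rate")
  epoc <- 1 + epoc_fraction
  structure(
    list(
      energy = rates$ee * bout_duration * epoc * KCAL_TO_KJ / 1000,
      o2 = rates$vo2 * bout_duration * epoc,
      co2 = rates$vco2 * bout_duration * epoc,
      heat = rates$mprod * bout_duration * 60 / 1000,
      sweat = sweat_rate * bout_duration
    ),
    class = "bout_totals"
  )
}

#' @export
print.bout_totals <- function(x, ...) {
  cat(sprintf(
    "<bout_totals> energy %.2f MJ, O2 %.1f L, CO2 %.1f L, heat %.0f kJ, sweat %.0f mL\n",
    x$energy, x$o2, x$co2, x$heat, x$sweat
  ))
  invisible(x)
}
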