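#' One person-day resource budget
#'
#' Assembles the 24-h totals for one crew member, without or with
#' countermeasure exercise.
#'
#' Without exercise: TEE = PAL x RMR + TEM; O2 and CO2 are the resting rates
#' scaled by PAL over 1440 min; heat is basal Mprod over 86,400 s
#' \emph{without} the PAL factor (the reading consistent with the reference
#' 24-h tables, where 24-h heat equals basal Mprod x 86,400 exactly); water
#' is the basal water budget.  With exercise, the prescribed bouts are added
#' on top of the full resting day (no deduction of resting metabolism during
#' exercise minutes).
#'
#' @param member A [crew_member()].
#' @param prescription An [exercise_prescription()], or `NULL` for a
#'   no-exercise day.
#' @param env A [cabin_environment()] (used for the sweat prediction).
#' @param pal Physical activity level.
#' @param tem_kcal Thermic effect of meals, kcal/d.
#' @param heat_variant `"basal"` (24-h heat = basal Mprod x 86,400, no PAL
#'   factor) or `"consistent"` (PAL factor applied to heat as well, making
#'   the heat row self-consistent with the O2 row).
#' @param iwn_basis Energy basis for insensible water, see
#'   [iwn_energy_needs()].
#' @param external_work_fraction Fraction of exercise Mprod exported as
#'   mechanical work (sweat prediction only).
#' @return An object of class `daily_budget`: `tee` (MJ), `o2`, `co2` (L),
#'   `heat` (MJ), `water` (L), `exercising` (logical), plus the underlying
#'   `bout` totals when exercising.
#' @examples
#' daily_budget(crew_member(1.70))
#' daily_budget(crew_member(1.70), exercise_prescription())
#' @export
daily_budget <- function(member, prescription = NULL,
                         env = cabin_environment(),
                         pal = DEFAULT_PAL,
                         tem_kcal = DEFAULT_TEM_KCAL,
                         heat_variant = c("basal", "consistent"),
                         iwn_basis = c("weir_rest", "tee"),
                         external_work_fraction = 0.2) {
  stopifnot(is_crew_member(member))
  heat_variant <- match.arg(heat_variant)
  iwn_basis <- match.arg(iwn_basis)
  profile <- resting_profile(member, pal = pal, tem_kcal = tem_kcal)

  heat_factor <- if (heat_variant == "basal") 1 else pal
  tee <- profile$rmr * pal + profile$tem
  o2 <- profile$vo2_rest * pal * MIN_PER_DAY
  co2 <- profile$vco2_rest * pal * MIN_PER_DAY
  heat <- profile$mprod_basal * heat_factor * SEC_PER_DAY / 1e6

  exercising <- !is.null(prescription) && prescription$bouts_per_day > 0
  bout <- NULL
  ex_energy <- 0
  sweat_l <- 0
  if (exercising) {
    rates <- exercise_rates(member, prescription$intensity_fraction)
    hb <- heat_balance(member, env, prescription$intensity_fraction,
                       external_work_fraction)
    bout <- bout_totals(rates, prescription$bout_duration,
                        prescription$epoc_fraction, hb$sweat_rate)
    n <- prescription$bouts_per_day
    ex_energy <- n * bout$energy
    tee <- tee + ex_energy
    o2 <- o2 + n * bout$o2
    co2 <- co2 + n * bout$co2
    heat <- heat + n * bout$heat / 1000
    sweat_l <- n * bout$sweat / 1000
  }
  wb <- water_budget(member, profile,
                     exercise_sweat_l = sweat_l,
                     basis = iwn_basis,
                     exercise_energy_mj = ex_energy)
  structure(
    list(
      tee = tee, o2 = o2, co2 = co2, heat = heat,
      water = wb$total_water,
      exercising = exercising,
      bout = bout,
      water_detail = wb
    ),
    class = "daily_budget"
  )
}

#' @export
print.daily_budget <- function(x, ...) {
  cat(sprintf(
    "<daily_budget%s> TEE %.1f MJ, O2 %.0f L, CO2 %.0f L, heat %.1f MJ, water %.2f L\n",
    if (x$exercising) ", exercising" else "", x$tee, x$o2, x$co2, x$heat, x$water
  ))
  invisible(x)
}

#' Mission scenario
#'
#' A roster of crew members, a mission duration, an optional exercise
#' prescription and the cabin environment.
#'
#' @param roster A list of [crew_member()] objects (non-empty).
#' @param duration Mission duration in days (> 0).
#' @param prescription An [exercise_prescription()] or `NULL`.
#' @param environment A [cabin_environment()].
#' @return An object of class `mission_scenario`.
#' @export
mission_scenario <- function(roster, duration, prescription = NULL,
                             environment = cabin_environment()) {
  if (is_crew_member(roster)) roster <- list(roster)
  if (!length(roster) || !all(vapply(roster, is_crew_member, logical(1)))) {
    stop_domain("roster", "must be a non-empty list of crew_member objects")
  }
  check_positive(duration, "duration")
  structure(
    list(
      roster = roster,
      duration = duration,
      prescription = prescription,
      environment = environment
    ),
    class = "mission_scenario"
  )
}

#' @export
print.mission_scenario <- function(x, ...) {
  cat(sprintf(
    "<mission_scenario> %d crew, %g d, %s\n",
    length(x$roster), x$duration,
    if (is.null(x$prescription)) "no exercise" else "with CM exercise"
  ))
  invisible(x)
}

# internal: number of exercise days under a d/week schedule
exercise_days <- function(duration, days_per_week, strict_schedule) {
  if (!strict_schedule || days_per_week >= 7) return(duration)
  full_weeks <- duration %/% 7
  remainder <- duration %% 7
  full_weeks * days_per_week + min(remainder, days_per_week)
}

#' Mission-level resource totals
#'
#' Sums per-person daily budgets over the roster and the mission duration.
#' By default exercise (when prescribed) is applied on every mission day —
#' the aggregation convention that reproduces the reference mission totals —
#' with `strict_schedule = TRUE` honouring the prescription's days-per-week
#' (exercise on the first `days_per_week` days of each 7-day block).
#'
#' @param scenario A [mission_scenario()].
#' @param strict_schedule Honour `days_per_week` < 7 (default `FALSE`).
#' @param ... Passed to [daily_budget()] (`pal`, `heat_variant`, ...).
#' @return An object of class `mission_totals`: `energy`, `heat` (MJ), `o2`,
#'   `co2`, `water` (L), plus `duration` and `n_crew`.
#' @examples
#' crew <- replicate(4, crew_member(1.50), simplify = FALSE)
#' mission_totals(mission_scenario(crew, 30))
#' @export
mission_totals <- function(scenario, strict_schedule = FALSE, ...) {
  stopifnot(inherits(scenario, "mission_scenario"))
  d <- scenario$duration
  presc <- scenario$prescription
  env <- scenario$environment
  ex_days <- if (is.null(presc)) 0 else {
    exercise_days(d, presc$days_per_week, strict_schedule)
  }
  acc <- c(energy = 0, o2 = 0, co2 = 0, heat = 0, water = 0)
  for (member in scenario$roster) {
    rest_day <- daily_budget(member, NULL, env, ...)
    rest_vec <- c(rest_day$tee, rest_day$o2, rest_day$co2, rest_day$heat,
                  rest_day$water)
    acc <- acc + rest_vec * d
    if (ex_days > 0) {
      ex_day <- daily_budget(member, presc, env, ...)
      ex_vec <- c(ex_day$tee, ex_day$o2, ex_day$co2, ex_day$heat, ex_day$water)
      acc <- acc + (ex_vec - rest_vec) * ex_days
    }
  }
  structure(
    list(energy = acc[["energy"]], o2 = acc[["o2"]], co2 = acc[["co2"]],
         heat = acc[["heat"]], water = acc[["water"]],
         duration = d, n_crew = length(scenario$roster)),
    class = "mission_totals"
  )
}

#' @export
print.mission_totals <- function(x, ...) {
  cat(sprintf(
    "<mission_totals> %d crew x %g d: energy %.0f MJ, O2 %.0f L, CO2 %.0f L, heat %.1f MJ, water %.0f L\n",
    x$n_crew, x$duration, x$energy, x$o2, x$co2, x$heat, x$water
  ))
  invisible(x)
}

#' Difference between two mission totals
#'
#' Elementwise `b - a` for the five resource fields; used for size- and
#' exercise-attributable deltas.
#'
#' @param a,b [mission_totals()] objects.
#' @return A named numeric vector with `energy`, `o2`, `co2`, `heat`,
#'   `water`.
#' @export
scenario_delta <- function(a, b) {
  stopifnot(inherits(a, "mission_totals"), inherits(b, "mission_totals"))
  c(energy = b$energy - a$energy,
    o2 = b$o2 - a$o2,
    co2 = b$co2 - a$co2,
    heat = b$heat - a$heat,
    water = b$water - a$water)
}

#' Crew heat load with one member exercising
#'
#' Worst-case instantaneous thermal load on the cabin when crew members
#' exercise consecutively: one member's exercising heat production plus the
#' remaining members' basal heat production.
#'
#' @param roster List of [crew_member()] (first member exercises).
#' @param intensity_fraction Exercise intensity, fraction of VO2max.
#' @return Total crew heat production in J/s.
#' @examples
#' crew <- replicate(4, crew_member(1.90), simplify = FALSE)
#' concurrent_exercise_heat(crew)  # ~1,386 J/s
#' @export
concurrent_exercise_heat <- function(roster, intensity_fraction = 0.75) {
  if (is_crew_member(roster)) roster <- list(roster)
  if (!length(roster) || !all(vapply(roster, is_crew_member, logical(1)))) {
    stop_domain("roster", "must be a non-empty list of crew_member objects")
  }
  ex <- exercise_rates(roster[[1]], intensity_fraction)$mprod
  rest <- 0
  if (length(roster) > 1) {
    rest <- sum(vapply(
      roster[-1],
      function(m) resting_profile(m)$mprod_basal,
      numeric(1)
    ))
  }
  ex + rest
}
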