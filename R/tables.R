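## Report tables over the reference stature grid.  All values are returned
## unrounded; run_pipeline() renders them at the printed precision.

#' Per-person characteristics across the stature grid
#'
#' One row per stature: derived anthropometrics, resting metabolism, basal
#' fluid needs, and steady-state exercise rates at the prescribed intensity.
#'
#' @param statures Stature grid, m.
#' @param env A [cabin_environment()].
#' @param intensity_fraction Exercise intensity, fraction of VO2max.
#' @param pal,tem_kcal Resting-profile parameters.
#' @param iwn_basis Energy basis for insensible water.
#' @param ... Passed to [crew_member()].
#' @return A data.frame with columns `stature`, `body_mass`, `bsa`,
#'   `vo2max_abs`, `rmr`, `neat`, `vo2_rest`, `vco2_rest`, `mprod_basal`,
#'   `basal_fluid`, `vo2_ex`, `vco2_ex`, `ee_ex`, `mprod_ex`, `sweat_rate`.
#' @export
characteristics_table <- function(statures = REFERENCE_STATURES,
                                  env = cabin_environment(),
                                  intensity_fraction = 0.75,
                                  pal = DEFAULT_PAL,
                                  tem_kcal = DEFAULT_TEM_KCAL,
                                  iwn_basis = "weir_rest",
                                  ...) {
  rows <- lapply(statures, function(s) {
    m <- crew_member(s, ...)
    p <- resting_profile(m, pal = pal, tem_kcal = tem_kcal)
    r <- exercise_rates(m, intensity_fraction)
    hb <- heat_balance(m, env, intensity_fraction)
    wb <- water_budget(m, p, basis = iwn_basis)
    data.frame(
      stature = s,
      body_mass = m$body_mass,
      bsa = m$bsa,
      vo2max_abs = m$vo2max_abs,
      rmr = p$rmr,
      neat = p$neat,
      vo2_rest = p$vo2_rest,
      vco2_rest = p$vco2_rest,
      mprod_basal = p$mprod_basal,
      basal_fluid = wb$basal_water,
      vo2_ex = r$vo2,
      vco2_ex = r$vco2,
      ee_ex = r$ee,
      mprod_ex = r$mprod,
      sweat_rate = hb$sweat_rate
    )
  })
  do.call(rbind, rows)
}

#' Single-bout totals across the stature grid
#'
#' @inheritParams characteristics_table
#' @param prescription An [exercise_prescription()].
#' @return A data.frame with `stature`, `energy_mj`, `o2_l`, `co2_l`,
#'   `heat_kj`, `sweat_ml` per bout.
#' @export
bout_table <- function(statures = REFERENCE_STATURES,
                       env = cabin_environment(),
                       prescription = exercise_prescription(),
                       ...) {
  rows <- lapply(statures, function(s) {
    m <- crew_member(s, ...)
    r <- exercise_rates(m, prescription$intensity_fraction)
    hb <- heat_balance(m, env, prescription$intensity_fraction)
    b <- bout_totals(r, prescription$bout_duration, prescription$epoc_fraction,
                     hb$sweat_rate)
    data.frame(
      stature = s,
      energy_mj = b$energy,
      o2_l = b$o2,
      co2_l = b$co2,
      heat_kj = b$heat,
      sweat_ml = b$sweat
    )
  })
  do.call(rbind, rows)
}

#' 24-h budgets across the stature grid, without and with exercise
#'
#' @inheritParams bout_table
#' @param heat_variant,iwn_basis See [daily_budget()].
#' @return A data.frame with `stature`, `exercise` (logical), `tee_mj`,
#'   `o2_l`, `co2_l`, `heat_mj`, `water_l`.
#' @export
daily_table <- function(statures = REFERENCE_STATURES,
                        env = cabin_environment(),
                        prescription = exercise_prescription(),
                        heat_variant = "basal",
                        iwn_basis = "weir_rest",
                        ...) {
  rows <- list()
  for (s in statures) {
    m <- crew_member(s, ...)
    for (ex in c(FALSE, TRUE)) {
      b <- daily_budget(
        m,
        prescription = if (ex) prescription else NULL,
        env = env,
        heat_variant = heat_variant,
        iwn_basis = iwn_basis
      )
      rows[[length(rows) + 1]] <- data.frame(
        stature = s, exercise = ex,
        tee_mj = b$tee, o2_l = b$o2, co2_l = b$co2,
        heat_mj = b$heat, water_l = b$water
      )
    }
  }
  do.call(rbind, rows)
}

#' Size- and exercise-attributable mission deltas
#'
#' Absolute increases in energy, O2, CO2, heat and water for a four-person
#' crew over 30-d and 1,080-d missions: the body-size effect (largest vs
#' smallest stature, no exercise) and the exercise effect at each end of the
#' stature range.
#'
#' @inheritParams daily_table
#' @param durations Mission durations, days.
#' @param n_crew Crew size.
#' @return A data.frame with one row per (duration, contrast).
#' @export
delta_table <- function(durations = c(30, 1080),
                        n_crew = REFERENCE_CREW_SIZE,
                        env = cabin_environment(),
                        prescription = exercise_prescription(),
                        ...) {
  lo <- min(REFERENCE_STATURES)
  hi <- max(REFERENCE_STATURES)
  make_totals <- function(stature, duration, exercise) {
    roster <- replicate(n_crew, crew_member(stature), simplify = FALSE)
    mission_totals(mission_scenario(
      roster, duration,
      prescription = if (exercise) prescription else NULL,
      environment = env
    ), ...)
  }
  rows <- list()
  for (d in durations) {
    small_rest <- make_totals(lo, d, FALSE)
    large_rest <- make_totals(hi, d, FALSE)
    small_ex <- make_totals(lo, d, TRUE)
    large_ex <- make_totals(hi, d, TRUE)
    contrasts <- list(
      body_size = scenario_delta(small_rest, large_rest),
      exercise_small = scenario_delta(small_rest, small_ex),
      exercise_large = scenario_delta(large_rest, large_ex),
      size_plus_exercise = scenario_delta(small_rest, large_ex)
    )
    for (nm in names(contrasts)) {
      v <- contrasts[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        duration = d, contrast = nm,
        energy_mj = v[["energy"]], o2_l = v[["o2"]], co2_l = v[["co2"]],
        heat_mj = v[["heat"]], water_l = v[["water"]]
      )
    }
  }
  do.call(rbind, rows)
}

#' Mission-total series across the full scenario grid
#'
#' Evaluates [mission_totals()] over the 5 x 6 x 2 reference grid; these are
#' the data behind the mission-duration figures.
#'
#' @inheritParams delta_table
#' @return A data.frame with `stature`, `duration`, `exercise`, `energy_mj`,
#'   `o2_l`, `co2_l`, `heat_mj`, `water_l`.
#' @export
figure_series <- function(env = cabin_environment(), ...) {
  grid <- reference_grid(environment = env)
  rows <- lapply(grid, function(sc) {
    tot <- mission_totals(sc, ...)
    data.frame(
      stature = attr(sc, "stature"),
      duration = sc$duration,
      exercise = attr(sc, "exercise"),
      energy_mj = tot$energy,
      o2_l = tot$o2,
      co2_l = tot$co2,
      heat_mj = tot$heat,
      water_l = tot$water
    )
  })
  do.call(rbind, rows)
}
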