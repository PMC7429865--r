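test_that("a no-exercise person-day reproduces the reference 24-h budget", {
  b <- daily_budget(crew_member(1.70))
  expect_printed(b$tee, 10.8, 0.1, k = 1)
  expect_printed(b$o2, 510, 1, k = 1)
  expect_printed(b$co2, 401, 1, k = 1)
  expect_printed(b$heat, 7.3, 0.1, k = 1)
  expect_false(b$exercising)
  # 24-h heat equals basal Mprod x 86,400 exactly under the default variant
  p <- resting_profile(crew_member(1.70))
  expect_equal(b$heat, p$mprod_basal * 86400 / 1e6)
  # the self-consistent variant applies the PAL factor to heat as well
  bc <- daily_budget(crew_member(1.70), heat_variant = "consistent")
  expect_equal(bc$heat, 1.4 * b$heat)
  expect_equal(bc$o2, b$o2)
})

test_that("an exercising person-day adds the prescribed bouts on top of the resting day", {
  m <- crew_member(1.70)
  rest <- daily_budget(m)
  ex <- daily_budget(m, exercise_prescription())
  expect_printed(ex$tee, 14.1, 0.1, k = 1)
  expect_printed(ex$co2, 544, 1, k = 1)
  expect_printed(ex$heat, 10.4, 0.1, k = 1)
  expect_true(ex$exercising)
  # with-exercise dominates the resting day in every field
  for (f in c("tee", "o2", "co2", "heat", "water")) {
    expect_gte(ex[[f]], rest[[f]])
  }
  expect_lt(ex$co2, ex$o2)  # RER < 1 throughout
  # additivity: exercising day = resting day + bouts
  expect_equal(ex$tee, rest$tee + 2 * ex$bout$energy)
  expect_equal(ex$o2, rest$o2 + 2 * ex$bout$o2)
  # zero-bout prescription degenerates to the resting day
  none <- daily_budget(m, exercise_prescription(bouts_per_day = 0))
  expect_equal(none$tee, rest$tee)
  expect_false(none$exercising)
})

test_that("mission totals reproduce the reference crew aggregates", {
  small30 <- mission_totals(mission_scenario(make_crew(1.50), 30))
  expect_printed(small30$energy, 1074, 1, k = 1)
  long <- mission_totals(mission_scenario(make_crew(1.50), 1080))
  expect_rel(long$energy, 38659, 0.001)
  large30 <- mission_totals(mission_scenario(make_crew(1.90), 30))
  expect_rel(large30$energy, 1548, 0.001)
})

test_that("mission totals are linear in duration and crew size", {
  sc <- function(n, d) mission_scenario(make_crew(1.70, n), d,
                                        exercise_prescription())
  t1 <- mission_totals(sc(4, 45))
  t2 <- mission_totals(sc(4, 90))
  t8 <- mission_totals(sc(8, 45))
  one <- mission_totals(sc(1, 45))
  for (f in c("energy", "o2", "co2", "heat", "water")) {
    expect_equal(t2[[f]], 2 * t1[[f]])
    expect_equal(t8[[f]], 2 * t1[[f]])
    expect_equal(t1[[f]], 4 * one[[f]])
  }
  # unit duration equals the crew sum of daily budgets
  d1 <- mission_totals(mission_scenario(make_crew(1.70), 1))
  day <- daily_budget(crew_member(1.70))
  expect_equal(d1$energy, 4 * day$tee)
  expect_equal(d1$o2, 4 * day$o2)
})

test_that("scenario deltas isolate size and exercise effects", {
  small <- mission_totals(mission_scenario(make_crew(1.50), 30))
  large <- mission_totals(mission_scenario(make_crew(1.90), 30))
  size <- scenario_delta(small, large)
  expect_printed(size[["energy"]], 475, 1, k = 1)
  expect_printed(size[["o2"]] / 1000, 28.8, 0.1, k = 1)
  zero <- scenario_delta(small, small)
  expect_true(all(zero == 0))
  large_ex <- mission_totals(mission_scenario(make_crew(1.90), 30,
                                              exercise_prescription()))
  combined <- scenario_delta(small, large_ex)
  expect_printed(combined[["o2"]] / 1000, 52.5, 0.1, k = 1)
  expect_printed(combined[["co2"]] / 1000, 44.0, 0.1, k = 1)
  expect_printed(combined[["heat"]], 874.2, 0.1, k = 1)
})

test_that("the strict 6-d/week schedule lowers totals by the missed days", {
  presc <- exercise_prescription(days_per_week = 6)
  sc <- mission_scenario(make_crew(1.50), 28, presc)
  daily <- mission_totals(sc)                       # exercise all 28 days
  strict <- mission_totals(sc, strict_schedule = TRUE)  # 24 of 28 days
  rest <- mission_totals(mission_scenario(make_crew(1.50), 28))
  ex_increment <- (daily$energy - rest$energy) / 28
  expect_equal(strict$energy, rest$energy + 24 * ex_increment)
  expect_lt(strict$o2, daily$o2)
})

test_that("concurrent exercise heat is one exercising plus n-1 resting members", {
  expect_printed(concurrent_exercise_heat(make_crew(1.90)), 1388, 1388 * 0.002,
                 k = 1)
  # single resting-free member: just the exercise term
  one <- concurrent_exercise_heat(list(crew_member(1.90)))
  expect_equal(one, exercise_rates(crew_member(1.90))$mprod)
  # hand-assembled small-crew value
  small <- concurrent_exercise_heat(make_crew(1.50))
  expect_equal(small,
               exercise_rates(crew_member(1.50))$mprod +
                 3 * resting_profile(crew_member(1.50))$mprod_basal)
  expect_error(concurrent_exercise_heat(list()), "roster")
})

test_that("every per-person daily quantity increases strictly with stature", {
  tab <- daily_table()
  for (ex in c(FALSE, TRUE)) {
    sub <- tab[tab$exercise == ex, ]
    for (col in c("tee_mj", "o2_l", "co2_l", "heat_mj", "water_l")) {
      expect_true(all(diff(sub[[col]]) > 0),
                  label = sprintf("%s (exercise=%s)", col, ex))
    }
  }
})
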