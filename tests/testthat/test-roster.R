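test_that("fixed rosters reproduce the reference homogeneous crews", {
  spec <- roster_spec(4, statures = rep(1.50, 4))
  roster <- generate_roster(spec)
  expect_length(roster, 4)
  expect_true(all(vapply(roster, function(m) m$stature == 1.50, logical(1))))
  expect_equal(roster[[1]]$body_mass, 59.625)
  expect_error(roster_spec(0), "n_crew")
})

test_that("identical seeds give identical rosters; different seeds differ", {
  spec <- function(seed) roster_spec(6, sampler = "uniform", seed = seed)
  r1 <- generate_roster(spec(42))
  r2 <- generate_roster(spec(42))
  expect_identical(
    vapply(r1, `[[`, numeric(1), "stature"),
    vapply(r2, `[[`, numeric(1), "stature")
  )
  r3 <- generate_roster(spec(43))
  expect_false(identical(
    vapply(r1, `[[`, numeric(1), "stature"),
    vapply(r3, `[[`, numeric(1), "stature")
  ))
  # roster generation does not disturb the global RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_roster(spec(42))); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("sampled statures respect their bounds and the law of large numbers", {
  spec <- roster_spec(1000, sampler = "uniform", lo = 1.50, hi = 1.90, seed = 1)
  s <- vapply(generate_roster(spec), `[[`, numeric(1), "stature")
  expect_true(all(s >= 1.50 & s <= 1.90))
  # uniform(1.50, 1.90) mean 1.70; MC standard error ~0.0037
  expect_lt(abs(mean(s) - 1.70), 0.012)
  tn <- roster_spec(500, sampler = "truncnorm", lo = 1.50, hi = 1.90,
                    mean = 1.70, sd = 0.07, seed = 2)
  st <- vapply(generate_roster(tn), `[[`, numeric(1), "stature")
  expect_true(all(st >= 1.50 & st <= 1.90))
})

test_that("bounds outside the agency stature band warn but do not fail", {
  expect_warning(roster_spec(4, sampler = "uniform", lo = 1.40, hi = 1.90),
                 "agency stature band")
  expect_silent(roster_spec(4, sampler = "uniform", lo = 1.50, hi = 1.90))
})

test_that("shared parameters propagate to every member", {
  spec <- roster_spec(3, statures = c(1.6, 1.7, 1.8),
                      shared_params = list(bmi = 24, age = 35))
  roster <- generate_roster(spec)
  expect_true(all(vapply(roster, function(m) m$bmi == 24, logical(1))))
  expect_equal(roster[[2]]$body_mass, 24 * 1.7^2)
})

test_that("the reference grid enumerates 5 statures x 6 durations x 2 regimes", {
  grid <- reference_grid()
  expect_length(grid, 60)
  statures <- vapply(grid, attr, numeric(1), "stature")
  durations <- vapply(grid, `[[`, numeric(1), "duration")
  exercise <- vapply(grid, attr, logical(1), "exercise")
  expect_setequal(unique(statures), c(1.50, 1.60, 1.70, 1.80, 1.90))
  expect_setequal(unique(durations), c(30, 90, 180, 360, 720, 1080))
  expect_equal(sum(exercise), 30)
  # each scenario is a homogeneous four-person crew
  expect_true(all(vapply(grid, function(sc) {
    length(sc$roster) == 4 &&
      length(unique(vapply(sc$roster, `[[`, numeric(1), "stature"))) == 1
  }, logical(1))))
})

test_that("homogeneous rosters reduce to per-member values times crew size", {
  tot4 <- mission_totals(mission_scenario(make_crew(1.80, 4), 10))
  tot1 <- mission_totals(mission_scenario(make_crew(1.80, 1), 10))
  for (f in c("energy", "o2", "co2", "heat", "water")) {
    expect_equal(tot4[[f]], 4 * tot1[[f]])
  }
})
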