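test_that("net metabolic heat subtracts external work and normalises to BSA", {
  expect_equal(net_metabolic_heat(857, 0.20, 1.88), 857 * 0.8 / 1.88)
  expect_equal(net_metabolic_heat(500, 0, 2.0), 250)
  expect_printed(net_metabolic_heat(1070, 0.20, 2.24), 382.1, 0.1, k = 1)
  expect_error(net_metabolic_heat(857, 1, 1.88), "external_work_fraction")
})

test_that("dry heat loss follows the resistance network", {
  env <- cabin_environment()
  # pinned regression constant for the default cabin (22 degC air, 35 degC
  # skin, 0.5 m/s, Icl 0.06): 13 degC over 0.06 + 1/((8.3*0.5^0.6 + 4.7)*1.1)
  expect_equal(dry_heat_loss(env), 87.0514, tolerance = 1e-4)
  # zero gradient gives zero loss
  env_eq <- cabin_environment(air_temp = 35)
  expect_equal(dry_heat_loss(env_eq), 0)
  # hot environment returns a gain (negative), not an error
  env_hot <- cabin_environment(air_temp = 36.5)
  expect_lt(dry_heat_loss(env_hot), 0)
  # doubling total resistance at fixed gradient halves the loss
  r_air <- 1 / ((8.3 * 0.5^0.6 + 4.7) * 1.1)
  env_double <- cabin_environment(
    clothing_thermal_resistance = 2 * (0.06 + r_air) - r_air
  )
  expect_equal(dry_heat_loss(env_double), dry_heat_loss(env) / 2,
               tolerance = 1e-12)
})

test_that("evaporative capacity responds to humidity and exceeds the legacy shuttle value", {
  env <- cabin_environment()
  # pinned regression constant for the default cabin
  expect_equal(emax(env), 207.356, tolerance = 1e-3)
  # no gradient: saturated air at skin temperature
  env0 <- cabin_environment(air_temp = 35, relative_humidity = 1,
                            skin_temp = 35 - 1e-9)
  expect_equal(emax(env0), 0, tolerance = 1e-4)
  # drier air strictly increases emax
  rh <- seq(0.9, 0.1, by = -0.1)
  em <- vapply(rh, function(h) emax(cabin_environment(relative_humidity = h)),
               numeric(1))
  expect_true(all(diff(em) > 0))
  # the 22 degC / 55% RH cabin clears more vapour than the legacy hot-humid
  # shuttle environment (27 degC, ~21 Torr ambient vapour pressure), so
  # skin wettedness for a given Ereq is lower
  legacy <- cabin_environment(air_temp = 27, relative_humidity = 0.785)
  expect_gt(emax(env), emax(legacy))
})

test_that("saturation vapour pressure matches handbook values", {
  # water boils at 100 degC: 760 mmHg = 101.32 kPa
  expect_equal(saturation_vapour_pressure(100), 760 * 0.133322,
               tolerance = 0.01)
  expect_equal(saturation_vapour_pressure(35), 5.608, tolerance = 1e-3)
  expect_equal(saturation_vapour_pressure(22), 2.635, tolerance = 1e-3)
})

test_that("predicted sweat rates track the reference envelope and monotonicity", {
  env <- cabin_environment()
  sr <- vapply(ref_statures, function(s) {
    heat_balance(crew_member(s), env)$sweat_rate
  }, numeric(1))
  # within the quantitative tolerance granted to the sweat surface
  expect_rel(sr, ref_t1$sweat_rate, 0.15)
  expect_true(all(diff(sr) > 0))
  # whole-range envelope with the same +/-15% slack
  expect_gt(min(sr), 10.1 * 0.85)
  expect_lt(max(sr), 17.1 * 1.15)
})

test_that("sweat prediction floors at zero cooling demand and rejects uncompensable input", {
  expect_equal(sweat_rate(0, 207.4, 1.88),
               max(147 - 0.87 * 207.4, 0) * 1.88 / 60)
  expect_gte(sweat_rate(0, 500, 1.88), 0)
  expect_error(sweat_rate(250, 0, 1.88), "emax")
  # monotone in metabolic drive at fixed environment
  sr <- vapply(seq(150, 350, by = 50), function(e) sweat_rate(e, 207.4, 1.88),
               numeric(1))
  expect_true(all(diff(sr) > 0))
})

test_that("heat balance chains Mnet, dry loss, Ereq and Emax coherently", {
  m <- crew_member(1.70)
  env <- cabin_environment()
  hb <- heat_balance(m, env)
  expect_equal(hb$ereq, hb$mnet - hb$dry_loss)
  expect_lt(hb$ereq, hb$mnet)
  expect_gt(hb$emax, 0)
  expect_equal(hb$wettedness, hb$ereq / hb$emax)
  expect_equal(hb$sweat_rate, sweat_rate(hb$ereq, hb$emax, m$bsa))
})
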