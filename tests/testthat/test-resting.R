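test_that("Harris-Benedict RMR reproduces the reference grid and the linear form", {
  expect_printed(rmr_harris_benedict(76.585, 1.70, 40), 7.13, 0.01)
  expect_printed(rmr_harris_benedict(59.625, 1.50, 40), 5.78, 0.01)
  # frozen arithmetic oracle at an off-grid anthropometry
  kcal <- 88.362 + 13.397 * 80 + 4.799 * 175.5 - 5.677 * 40
  expect_equal(rmr_harris_benedict(80, 1.755, 40), kcal * 4.1868 / 1000,
               tolerance = 1e-12)
  # sign structure of the linear form
  expect_gt(rmr_harris_benedict(85, 1.70, 40), rmr_harris_benedict(80, 1.70, 40))
  expect_gt(rmr_harris_benedict(80, 1.75, 40), rmr_harris_benedict(80, 1.70, 40))
  expect_lt(rmr_harris_benedict(80, 1.70, 50), rmr_harris_benedict(80, 1.70, 40))
  expect_error(rmr_harris_benedict(80, 1.70, 0), "age")
  expect_error(rmr_harris_benedict(80, 1.70, 120), "age")
})

test_that("NEAT is (PAL - 1) x RMR with a sedentary floor", {
  expect_printed(neat_from_pal(7.1306, 1.4), 2.85, 0.01)
  expect_printed(neat_from_pal(8.6027, 1.4), 3.44, 0.01)
  expect_equal(neat_from_pal(7.5, 1.0), 0)
  expect_error(neat_from_pal(7.5, 0.9), "pal")
})

test_that("resting gas exchange scales with mass and RER", {
  g <- resting_gas_exchange(76.585, 3.3, 0.788)
  expect_printed(g$vo2, 0.253, 0.001)
  expect_printed(g$vco2, 0.199, 0.001)
  g2 <- resting_gas_exchange(95.665, 3.3, 0.788)
  expect_printed(g2$vo2, 0.316, 0.001)
  expect_printed(g2$vco2, 0.249, 0.001)
  # unit RER makes VCO2 = VO2; ratio equals RER everywhere
  gu <- resting_gas_exchange(70, 3.3, 1)
  expect_equal(gu$vco2, gu$vo2)
  for (mass in c(60, 75, 95)) {
    gi <- resting_gas_exchange(mass, 3.3, 0.788)
    expect_equal(gi$vco2 / gi$vo2, 0.788)
  }
})

test_that("heat production converts oxygen uptake at the thermal equivalent", {
  expect_printed(mprod(0.2528, 4.788), 84.4, 0.1, k = 1)
  expect_equal(mprod(0, 4.788), 0)
  expect_printed(mprod(1.940, 4.924), 667, 1, k = 1)
  # 0.01433 is the kcal/min -> W conversion: 1 L/min at 4.788 kcal/L is
  # 4.788 kcal/min = 4.788 * 4186.8 / 60 W
  expect_equal(mprod(1, 4.788), 4.788 * 4186.8 / 60, tolerance = 1e-4)
})

test_that("resting profile is internally consistent", {
  m <- crew_member(1.70)
  p <- resting_profile(m)
  expect_equal(p$neat, (p$pal - 1) * p$rmr)
  expect_equal(p$vco2_rest, m$rer_rest * p$vo2_rest)
  expect_equal(p$tem, 206 * 4.1868 / 1000)
  expect_true(all(unlist(p[c("rmr", "neat", "tem", "vo2_rest", "vco2_rest",
                             "mprod_basal")]) > 0))
})

test_that("24-h basal heat and Harris-Benedict RMR agree at mid-stature and diverge with size", {
  # two independent routes to resting energy: thermal-equivalent-of-O2 heat
  # vs the Harris-Benedict equation
  p <- resting_profile(crew_member(1.70))
  heat_mj <- p$mprod_basal * 86400 / 1e6
  expect_lt(abs(heat_mj - p$rmr) / p$rmr, 0.03)
  # the VO2 route is proportional to mass while Harris-Benedict is affine,
  # so the gap grows monotonically across the stature range
  gap <- vapply(ref_statures, function(s) {
    pp <- resting_profile(crew_member(s))
    (pp$mprod_basal * 86400 / 1e6 - pp$rmr) / pp$rmr
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_lt(max(abs(gap)), 0.06)
})
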