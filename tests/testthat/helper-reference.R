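# Published reference values for the five-stature male astronaut grid.
# These are the golden values the package is expected to reproduce.

ref_statures <- c(1.50, 1.60, 1.70, 1.80, 1.90)

# per-person characteristics (one value per stature, ascending)
ref_t1 <- list(
  body_mass   = c(59.6, 67.8, 76.6, 85.9, 95.7),       # kg
  bsa         = c(1.54, 1.71, 1.88, 2.06, 2.24),       # m^2
  vo2max_abs  = c(2.59, 2.94, 3.32, 3.73, 4.15),       # L/min
  rmr         = c(5.78, 6.44, 7.13, 7.85, 8.60),       # MJ/d
  neat        = c(2.31, 2.58, 2.85, 3.14, 3.44),       # MJ/d
  vo2_rest    = c(0.197, 0.224, 0.253, 0.283, 0.316),  # L/min
  vco2_rest   = c(0.155, 0.176, 0.199, 0.223, 0.249),  # L/min
  mprod_basal = c(65.7, 74.8, 84.4, 94.7, 105.5),      # J/s
  basal_fluid = c(2.63, 2.74, 2.86, 2.99, 3.13),       # L/d
  vo2_ex      = c(1.94, 2.21, 2.49, 2.79, 3.11),       # L/min
  vco2_ex     = c(1.74, 1.98, 2.24, 2.51, 2.80),       # L/min
  ee_ex       = c(9.6, 10.9, 12.3, 13.8, 15.4),        # kcal/min
  mprod_ex    = c(667, 759, 857, 960, 1070),           # J/s
  sweat_rate  = c(10.1, 11.7, 13.4, 15.2, 17.1)        # mL/min
)

# single 30-min bout at 75% VO2max
ref_t2 <- list(
  energy = c(1.28, 1.45, 1.64, 1.84, 2.05),            # MJ
  o2     = c(61.7, 70.2, 79.3, 88.9, 99.0),            # L
  co2    = c(55.4, 63.1, 71.2, 79.8, 88.9),            # L
  heat   = c(1200, 1366, 1542, 1729, 1926),            # kJ
  sweat  = c(303, 350, 401, 455, 513)                  # mL
)

# 24-h budgets; the 1.50 m with-exercise TEE is 11.5 (the published 11.9 is
# a typo: it contradicts the published +29% bracket, the +306 MJ 30-d
# exercise delta and the 11,019 MJ 1,080-d delta, all of which give 11.5)
ref_t3_rest <- list(
  tee   = c(8.9, 9.9, 10.8, 11.9, 12.9),               # MJ
  o2    = c(397, 451, 510, 571, 636),                  # L
  co2   = c(313, 356, 401, 450, 501),                  # L
  heat  = c(5.7, 6.5, 7.3, 8.2, 9.1),                  # MJ
  water = c(2.63, 2.74, 2.86, 2.99, 3.13)              # L
)
ref_t3_ex <- list(
  tee   = c(11.5, 12.8, 14.1, 15.5, 17.0),             # MJ
  vco2  = c(423, 482, 544, 610, 679),                  # L
  heat  = c(8.1, 9.2, 10.4, 11.6, 13.0),               # MJ
  water = c(3.23, 3.44, 3.67, 3.90, 4.16)              # L
)

# four-person homogeneous crew, convenience builder
make_crew <- function(stature, n = 4) {
  replicate(n, crew_member(stature), simplify = FALSE)
}

# compare a computed vector against printed values to within `k` units in
# the last printed digit (k = 0.5 is strict half-ulp rounding agreement;
# k = 1 tolerates the source's own rounding of intermediate values)
expect_printed <- function(actual, printed, ulp, k = 0.5) {
  expect_true(
    all(abs(actual - printed) <= k * ulp + 1e-9),
    label = sprintf(
      "max |actual - printed| = %.4g (allowed %.4g)",
      max(abs(actual - printed)), k * ulp
    )
  )
}

expect_rel <- function(actual, printed, tol) {
  expect_true(
    all(abs(actual - printed) / abs(printed) <= tol),
    label = sprintf(
      "max relative error = %.3f%% (allowed %.3f%%)",
      100 * max(abs(actual - printed) / abs(printed)), 100 * tol
    )
  )
}
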