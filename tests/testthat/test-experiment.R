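test_that("the factorial design enumerates the full run count", {
  g <- design_grid()
  expect_equal(nrow(g), 8 * 4 * 9 * 5 * 2)
  expect_equal(attr(g, "n_runs"), 1440000)
  # a tenfold reduction of the seal replicates
  expect_equal(attr(design_grid(n_seals = 5), "n_runs"), 144000)
})

test_that("condition runs are reproducible and order-independent", {
  p <- cpf_params()
  r1 <- run_condition(3, 180, 150, 115, 1L, n_maps = 2, n_seals = 3,
                      seed = 5, params = p)
  r2 <- run_condition(3, 180, 150, 115, 1L, n_maps = 2, n_seals = 3,
                      seed = 5, params = p)
  expect_identical(r1, r2)
  s <- summarize_condition(r1)
  expect_equal(s$sp, pair_success(s$d_f, s$d_p), tolerance = 1e-12)
  expect_equal(s$n_runs, 6)
})

test_that("the cost/benefit ratio follows its definition", {
  expect_equal(cost_benefit(1000, 0.5), 2000)
  expect_equal(cost_benefit(c(500, 1500), 1), 1000)
  expect_identical(cost_benefit(1000, 0), Inf)
  expect_lt(cost_benefit(1000, 0.9), cost_benefit(1000, 0.4))
  expect_error(cost_benefit(-5, 0.5))
  expect_error(cost_benefit(100, 1.5))
})

test_that("the fitted optimum recovers a symmetric minimum and the printed vertex", {
  # run-level records with R(l) symmetric about 115: optimum at 115
  lens <- rep(c(85, 100, 115, 130, 145), each = 20)
  runs <- data.frame(length = lens,
                     e_spent = 10 + (lens - 115)^2 / 10,
                     female_survived = TRUE, pup_survived = TRUE)
  bo <- bootstrap_optimum(runs, n_boot = 50)
  expect_equal(bo$optimal_length, 115, tolerance = 0.5)
  # bootstrap of a constant sample has a zero-width interval
  expect_equal(bo$ci_low, bo$ci_high, tolerance = 1e-9)
  expect_equal(bo$ci_low, 115, tolerance = 0.5)
  # vertex of the printed quadratic 1.792 L^2 - 355.4 L + 19670
  lens5 <- c(85, 100, 115, 130, 145)
  r5 <- 1.792 * lens5^2 - 355.4 * lens5 + 19670
  expect_equal(cpforage:::curve_argmin(lens5, r5), 355.4 / (2 * 1.792),
               tolerance = 0.1)   # 99.16 cm
})

test_that("the optimal-length regression recovers exact synthetic slopes", {
  optima <- data.frame(dist = seq(150, 400, by = 50),
                       optimal_length = 0.128 * seq(150, 400, by = 50) + 80)
  reg <- optimal_length_regression(optima)
  expect_equal(reg$slope, 0.128, tolerance = 1e-9)
  # the implied body-length drift at a 3 km/year shift of the feeding grounds
  expect_equal(reg$drift_cm_per_year, 0.384, tolerance = 1e-9)
  expect_error(optimal_length_regression(optima[1:2, ]), "three")
})

test_that("condition summaries filter survivors as documented", {
  runs <- data.frame(
    aggreg = 3, abund = 180, dist = 150, length = 115, mem = 1,
    rep_map = rep(1:2, each = 2), rep = rep(1:2, 2),
    female_survived = c(TRUE, FALSE, TRUE, TRUE),
    pup_survived = c(TRUE, FALSE, FALSE, TRUE),
    final_mass_female = c(30, 10, 31, 32),
    final_mass_pup = c(11, NA, 4, 12),
    e_spent = c(1000, 400, 1100, 900),
    n_trips = c(10, 2, 12, 14),
    mean_d_trip = c(500, 100, 600, 550),
    mean_t_trip = c(80, 20, 90, 85),
    n_fishing = c(150, 10, 170, 160),
    mean_e_fish = c(6, 2, 7, 6.5),
    e_won_per_trip = c(60, 5, 70, 65))
  s <- summarize_condition(runs)
  # mortalities per map then averaged: map1 d_f = 0.5, map2 d_f = 0
  expect_equal(s$d_f, mean(c(0.5, 0)))
  expect_equal(s$d_p, mean(c(0.5, 0.5)))
  # behavioural means over females that completed the rearing period
  expect_equal(s$mean_d_trip, mean(c(500, mean(c(600, 550)))))
  # pup mass over surviving pups only
  expect_equal(s$mass_pup, mean(c(11, 12)))
})
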