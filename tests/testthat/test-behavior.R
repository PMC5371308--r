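test_that("fishing probability has its published anchors", {
  p <- cpf_params()
  th <- 4
  expect_equal(p_fishing(th, th, TRUE, FALSE, p), 0.5)
  expect_equal(p_fishing(10, th, FALSE, FALSE, p), 0)       # day
  expect_equal(p_fishing(1.4, th, TRUE, FALSE, p), 0)       # not profitable
  expect_equal(p_fishing(10, th, TRUE, TRUE, p), 0)         # satiated
  expect_equal(p_fishing(th + 2, th, TRUE, FALSE, p),
               exp(4) / (1 + exp(4)), tolerance = 1e-12)    # 0.9820
  a <- seq(1.5, 20, by = 0.5)
  expect_true(all(diff(p_fishing(a, th, TRUE, FALSE, p)) > 0))
  expect_true(all(p_fishing(a, th, TRUE, FALSE, p) >= 0 &
                    p_fishing(a, th, TRUE, FALSE, p) <= 1))
})

test_that("the fishing threshold runs from the profitability floor to AvgEnv", {
  p <- cpf_params()
  ae <- 4.9
  expect_equal(compute_th_t(ae, 1), p$min_fish_abund)       # at the floor
  expect_equal(compute_th_t(ae, p$thr_ceiling), ae)         # at satiety
  expect_gt(compute_th_t(ae, 1.5), compute_th_t(ae, 1.1))   # monotone
  r <- seq(1, p$thr_ceiling, length.out = 20)
  th <- compute_th_t(ae, r)
  expect_true(all(diff(th) >= 0))
  expect_true(all(th >= p$min_fish_abund & th <= ae + 1e-12))
  expect_error(compute_th_t(-1, 1.2))
})

test_that("the turning-angle spread reproduces the heading autocorrelation", {
  p <- cpf_params()
  set.seed(5)
  h <- numeric(10000)
  h[1] <- 0
  for (i in 2:10000) h[i] <- crw_step(h[i - 1], p)
  # lag-1 autocorrelation of headings (mean cosine of the hourly turn)
  lag_ac <- function(k) mean(cos(h[-seq_len(k)] - h[seq_len(10000 - k)]))
  expect_gt(lag_ac(1), 0.25)
  expect_lt(lag_ac(1), 0.35)
  expect_lt(abs(lag_ac(5)), 0.05)
  # limits: no spread means straight-line travel
  p0 <- cpf_params(crw_turn_sd = 0)
  expect_equal(crw_step(1.2, p0), 1.2)
  # enormous spread means a uniform turn: headings decorrelate immediately
  pu <- cpf_params(crw_turn_sd = 50)
  set.seed(6)
  hu <- Reduce(function(a, b) crw_step(a, pu), 1:2000, accumulate = TRUE)
  expect_lt(abs(mean(cos(diff(hu)))), 0.05)
})

test_that("heading choice follows the mode contracts", {
  p <- cpf_params()
  expect_equal(choose_heading("transit", target_bearing = 1.1, params = p), 1.1)
  expect_error(choose_heading("transit", target_bearing = NA, params = p))
  expect_equal(bearing(0, 0, 10, 0), 0)
  expect_equal(bearing(0, 0, 0, 10), pi / 2)
  # a positive gradient sensed to the east biases the mean heading east
  set.seed(9)
  hs <- replicate(1000, choose_heading("search", heading = runif(1, -pi, pi),
                                       gradient_bearing = 0, params = p))
  mean_dir <- atan2(mean(sin(hs)), mean(cos(hs)))
  expect_lt(abs(mean_dir), pi / 4)
  # naive headings are roughly uniform
  set.seed(10)
  hn <- replicate(2000, choose_heading("naive", params = p))
  expect_lt(abs(mean(cos(hn))), 0.06)
  expect_lt(abs(mean(sin(hn))), 0.06)
})

test_that("the return probability honours its boundaries and monotonicities", {
  p <- cpf_params()
  expect_equal(p_return(0.5, 0.5, 0.1, p), 1)    # cannot afford to stay
  expect_equal(p_return(0.4, 0.6, 0.1, p), 1)
  expect_equal(p_return(0.95, 0.2, 1, p), 1)     # trip-length ceiling
  expect_lt(p_return(0.93, 0.68, 0.1, p), 0.05)  # fresh, full female
  # three monotonicities on a 10 x 10 x 10 grid
  e <- seq(0.3, 1, length.out = 10)
  w <- seq(0, 0.9, length.out = 10)
  ts <- seq(0, 1, length.out = 10)
  for (wi in w) for (ti in ts)
    expect_true(all(diff(p_return(e, wi, ti, p)) <= 1e-12))
  for (ei in e) for (ti in ts)
    expect_true(all(diff(p_return(ei, w, ti, p)) >= -1e-12))
  for (ei in e) for (wi in w)
    expect_true(all(diff(p_return(ei, wi, ts, p)) >= -1e-12))
  expect_error(p_return(-0.1, 0.5, 0.5, p))
})

test_that("departures are scheduled to reach the target at night", {
  p <- cpf_params()
  expect_equal(departure_hour_for(NA, p), 17L)
  # memorised cell 76 km away: 10-11 h of travel; arrival must fall at night
  dep <- departure_hour_for(76, p)
  arr <- (dep + ceiling(76 / p$step_km)) %% 24
  expect_true(arr >= p$night_start || arr < 6)
  expect_equal(dep, 17L)   # 17:00 is itself feasible here
  # any target distance gives a night arrival
  for (d in seq(20, 480, by = 40)) {
    dep <- departure_hour_for(d, p)
    arr <- (dep + ceiling(d / p$step_km)) %% 24
    expect_true(arr >= p$night_start || arr < 6)
  }
  expect_equal(decide_departure(17, 12, NA, p), "stay")   # < 1 day ashore
  expect_equal(decide_departure(17, 49, NA, p), "leave")
  expect_equal(decide_departure(16, 49, NA, p), "stay")
})

test_that("memory keeps the strictly richest cell and fidelity saturates", {
  mem <- list(best_x = 100, best_y = 100, best_abundance = 5,
              last_trip_gain_rate = NA)
  m2 <- update_memory(mem, 200, 200, 7)
  expect_equal(c(m2$best_x, m2$best_y, m2$best_abundance), c(200, 200, 7))
  m3 <- update_memory(m2, 300, 300, 7)     # ties do not replace
  expect_equal(c(m3$best_x, m3$best_y), c(200, 200))
  m4 <- update_memory(m3, 300, 300, 3)
  expect_equal(m4$best_abundance, 7)
  p <- cpf_params()
  expect_equal(trip_fidelity(0, p), 0)                     # failed trip
  expect_equal(trip_fidelity(p$g_half, p), 0.5)
  expect_true(all(diff(trip_fidelity(seq(0, 3, 0.1), p)) > 0))
  expect_lt(trip_fidelity(100, p), 1)
})

test_that("compiled decision formulas agree with their R counterparts", {
  p <- cpf_params()
  for (ab in c(0, 1.4, 1.5, 3, 4.9, 12)) {
    expect_equal(cpforage:::cpp_p_fishing(ab, 4.2, TRUE, FALSE,
                                          p$min_fish_abund),
                 p_fishing(ab, 4.2, TRUE, FALSE, p), tolerance = 1e-12)
  }
  for (r in c(1, 1.1, 1.3, p$thr_ceiling, 2)) {
    expect_equal(cpforage:::cpp_th_t(4.9, r, p$thr_ceiling, p$min_fish_abund,
                                     p$th_exponent),
                 compute_th_t(4.9, r, p), tolerance = 1e-12)
  }
  for (e in c(0.4, 0.7, 0.95)) for (ts in c(0, 0.5, 1)) {
    expect_equal(cpforage:::cpp_p_return(e, 0.65, ts, p$return_k,
                                         p$return_gamma),
                 p_return(e, 0.65, ts, p), tolerance = 1e-12)
  }
  for (pct in c(50, 70, 80, 100)) {
    expect_equal(cpforage:::cpp_p_death(pct, 100, 70, p$mort_sd_pct),
                 p_death(pct, 100, "female", p), tolerance = 1e-12)
  }
})
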