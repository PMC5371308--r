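test_that("simulations are bit-reproducible given the seed", {
  m <- ref_map()
  s1 <- run_simulation(m, 115, 1, seed = 42)
  s2 <- run_simulation(m, 115, 1, seed = 42)
  for (f in c("female_survived", "pup_survived", "final_mass_female",
              "final_mass_pup", "total_energy_spent", "total_distance",
              "n_fishing_total", "hours_simulated"))
    expect_identical(s1[[f]], s2[[f]])
  expect_identical(s1$trips, s2$trips)
  s3 <- run_simulation(m, 115, 1, seed = 43)
  expect_false(identical(s1$total_energy_spent, s3$total_energy_spent))
})

test_that("the rearing clock runs exactly 2880 hourly steps for survivors", {
  m <- ref_map()
  found <- FALSE
  for (sd in 1:30) {
    s <- run_simulation(m, 115, 1, seed = sd)
    expect_lte(s$rearing_hours, 2880)
    if (s$female_survived && s$pup_survived) {
      expect_equal(s$rearing_hours, 2880)
      found <- TRUE
    }
  }
  expect_true(found)
})

test_that("a starvation landscape kills the pair before weaning", {
  p <- cpf_params()
  v <- matrix(0, 100, 100)
  v[20, 20] <- 2   # a single marginal cell far to one side
  m <- toy_map(v, p)
  deaths <- sapply(1:10, function(sd) {
    s <- run_simulation(m, 115, 1, seed = sd, params = p)
    !s$female_survived && !s$pup_survived
  })
  expect_true(all(deaths))
})

test_that("the hourly energy ledger balances exactly", {
  m <- ref_map()
  s <- run_simulation(m, 115, 1, seed = 7, trace = TRUE)
  tm <- as.data.frame(s$trace)
  # after the prospection pass (behavioural initialisation), every hourly
  # energy change decomposes into gain - metabolism - drag - transfer
  live <- which(tm$phase >= 1 & tm$t > 0)
  live <- live[live > 1]
  delta <- tm$e_seal[live] - tm$e_seal[live - 1]
  expected <- tm$gain[live] - tm$met[live] - tm$drag[live] - tm$transfer[live]
  # rows where the female is dead or energy clamps at zero are exempt
  ok <- tm$e_seal[live] > 0 &
    (tm$t[live] > s$death_hour_female | s$death_hour_female < 0)
  # the energy reset at the first rearing hour and the hour on which the
  # prospection pass ends are initialisation boundaries, not energy flow
  first_rear <- min(tm$t[tm$phase == 2])
  ok <- ok & tm$t[live] != first_rear & tm$phase[live - 1] != 0
  expect_lt(max(abs(delta[ok] - expected[ok])), 1e-9)
})

test_that("trip accounting is consistent with the totals", {
  m <- ref_map()
  s <- run_simulation(m, 115, 1, seed = 12)
  tr <- s$trips[s$trips$phase == 2, , drop = FALSE]
  expect_true(all(tr$t_end > tr$t_start))
  expect_true(all(tr$distance >= 0))
  # completed-trip tallies never exceed the running totals (an open trip at
  # day 120 contributes to the totals only)
  expect_lte(sum(tr$n_fishing), s$n_fishing_total)
  expect_lte(sum(tr$distance), s$total_distance + 1e-6)
  expect_true(all(tr$e_won >= 0))
  # trips do not overlap in time
  if (nrow(tr) > 1)
    expect_true(all(tr$t_start[-1] >= tr$t_end[-nrow(tr)]))
})

test_that("a dead female leaves a starving pup that the clock keeps tracking", {
  # harsh conditions: low abundance far from the colony
  p <- cpf_params()
  m <- generate_resource_map(1, 90, 450, seed = 2, params = p)
  seen <- FALSE
  for (sd in 1:25) {
    s <- run_simulation(m, 115, 1, seed = sd, params = p)
    if (!s$female_survived && s$death_hour_female >= 0 && s$pup_born &&
        !s$pup_survived && s$death_hour_pup > s$death_hour_female) {
      seen <- TRUE
      break
    }
  }
  expect_true(seen)
})

test_that("final states respect the physical bounds", {
  m <- ref_map()
  p <- cpf_params()
  for (sd in 1:10) {
    s <- run_simulation(m, 115, 1, seed = 100 + sd, params = p)
    expect_gte(s$final_mass_female, 0)
    if (!is.na(s$final_mass_pup)) {
      expect_gte(s$final_mass_pup, 0)
      expect_lte(s$final_mass_pup, p$pup_max_mass + 1e-9)
    }
    expect_gte(s$total_energy_spent, 0)
  }
})

test_that("trip durations under reference conditions span the plausible range", {
  m <- ref_map()
  durs <- c()
  for (sd in 1:20) {
    s <- run_simulation(m, 115, 1, seed = 200 + sd)
    tr <- s$trips[s$trips$phase == 2, , drop = FALSE]
    if (s$female_survived && nrow(tr)) durs <- c(durs, tr$t_end - tr$t_start)
  }
  expect_gt(mean(durs) / 24, 1)    # longer than a day on average
  expect_lt(mean(durs) / 24, 9)    # below the trip-length ceiling
})

test_that("fishing effort concentrates on the richest cells", {
  # optimal-foraging property: per-cell fishing frequency correlates
  # positively with cell abundance
  m <- ref_map()
  hm <- fishing_heatmap(m, n_seals = 25, length = 115, mem = 1, seed = 3)
  expect_gt(nrow(hm), 20)
  ct <- suppressWarnings(
    cor.test(hm$n_events, hm$abundance, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
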