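#' Run one full simulation
#'
#' Simulates one female-pup pair over a resource landscape: the 15-day
#' prospective prenatal period (exploration and memorisation), birth, the
#' perinatal shore fast (5-7 days), and the 120-day (2880 h) rearing period
#' during which the female alternates foraging trips and shore visits. The
#' time step is one hour with a 16 h / 8 h day-night alternation; each hour
#' applies the movement/decision update, the energy ledger and the hourly
#' mortality draws. Results are deterministic given `seed`.
#'
#' @param map a `resource_map` from [generate_resource_map()] (or
#'   [read_resource_map()]).
#' @param length female body length, cm (85, 100, 115, 130 or 145).
#' @param mem memory type, 0 or 1.
#' @param seed integer seed.
#' @param params parameter list from [cpf_params()].
#' @param trace if `TRUE`, attach an hourly trace matrix (time, phase,
#'   position, energies, event code and the hourly energy-ledger components).
#' @return An object of class `cpf_sim`: a list with survival flags, final
#'   masses (kg), total energy spent over the rearing period (MJ), total
#'   distance (km), fishing-event count, a `trips` data frame (one row per
#'   completed trip: phase, start/end hour, distance, fishing events, energy
#'   gained) and, optionally, the `trace` matrix.
#' @examples
#' m <- generate_resource_map(aggreg = 3, abund = 180, dist = 150, seed = 1)
#' s <- run_simulation(m, length = 115, mem = 1, seed = 42)
#' s
#' @export
run_simulation <- function(map, length = 115, mem = 1L, seed = 1L,
                           params = cpf_params(), trace = FALSE) {
  stopifnot(inherits(map, "resource_map"))
  fem <- init_female(length, map, mem, params)  # validates length/mem
  pl <- list(
    grid_n = params$grid_n, cell_km = params$cell_km,
    step_km = params$step_km, met_mj_kg = params$met_mj_kg,
    ashore_met_frac = params$ashore_met_frac,
    econtent_seal = params$econtent_seal, econtent_pup = params$econtent_pup,
    drag_km = drag_per_km(length, params),
    e_init = fem$e_init, e_min = fem$e_min,
    emax_factor = params$emax_factor, satiation_frac = params$satiation_frac,
    mj_per_unit = params$mj_per_unit, min_fish_abund = params$min_fish_abund,
    thr_ceiling = params$thr_ceiling, th_exponent = params$th_exponent,
    night_start = params$night_start, night_len = params$night_len,
    departure_hour = params$departure_hour,
    mta_h = params$mta_h, prenatal_ashore_h = params$prenatal_ashore_h,
    t_max_trip_h = params$t_max_trip_h,
    return_k = params$return_k, return_gamma = params$return_gamma,
    satiety_return_frac = params$satiety_return_frac,
    emergency_frac = params$emergency_frac,
    crw_turn_sd = params$crw_turn_sd,
    outbound_turn_sd = params$outbound_turn_sd,
    grad_weight = params$grad_weight,
    g_half = params$g_half, milk_rate = params$milk_rate,
    mem_dist_discount = params$mem_dist_discount,
    prospect_th_factor = params$prospect_th_factor,
    pup_e0 = params$pup_init_mass * params$econtent_pup,
    pup_max_e = params$pup_max_mass * params$econtent_pup,
    perinatal_gain_e = params$perinatal_gain * params$econtent_pup,
    pup_loss = params$pup_loss_per_hour,
    lethal_pct_female = params$lethal_pct_female,
    lethal_pct_pup = params$lethal_pct_pup,
    mort_sd_pct = params$mort_sd_pct,
    prenatal_h = as.integer(params$prenatal_days * 24),
    t_rearing_h = as.integer(params$t_rearing_h),
    mem = as.integer(mem),
    island_x = fem$x, island_y = fem$y)
  set.seed(seed)
  res <- sim_run_cpp(map$values, map$avg_env, pl, trace)
  res$trips <- as.data.frame(res$trips)
  res$length <- length
  res$mem <- as.integer(mem)
  res$seed <- as.integer(seed)
  res$map_config <- map$config
  class(res) <- "cpf_sim"
  res
}

#' @export
print.cpf_sim <- function(x, ...) {
  cat("cpf_sim: female", x$length, "cm, mem", x$mem, "| map aggreg",
      x$map_config$aggreg, "abund", x$map_config$abund, "dist",
      x$map_config$dist, "\n")
  cat(sprintf("  female %s (final mass %.2f kg), pup %s (final mass %s kg)\n",
              if (x$female_survived) "survived" else "died",
              x$final_mass_female,
              if (x$pup_survived) "survived" else "died",
              if (is.na(x$final_mass_pup)) "NA" else
                sprintf("%.2f", x$final_mass_pup)))
  nt <- sum(x$trips$phase == 2)
  cat(sprintf("  rearing trips: %d, fishing events: %d, energy spent: %.0f MJ\n",
              nt, x$n_fishing_total, x$total_energy_spent))
  invisible(x)
}

#' Per-run summary of the rearing-phase trips
#'
#' @param sim a `cpf_sim`.
#' @return One-row data frame: trips completed during rearing, mean trip
#'   distance (km), mean trip duration (h), total fishing events, mean energy
#'   per fishing event (MJ), energy gained per trip (MJ).
#' @export
trip_summary <- function(sim) {
  tr <- sim$trips[sim$trips$phase == 2, , drop = FALSE]
  n <- nrow(tr)
  data.frame(
    n_trips = n,
    mean_d_trip = if (n) mean(tr$distance) else NA_real_,
    mean_t_trip = if (n) mean(tr$t_end - tr$t_start) else NA_real_,
    n_fishing = if (n) sum(tr$n_fishing) else 0,
    mean_e_fish = if (n && sum(tr$n_fishing) > 0)
      sum(tr$e_won) / sum(tr$n_fishing) else NA_real_,
    e_won_per_trip = if (n) mean(tr$e_won) else NA_real_)
}

#' Fishing locations of a traced run
#'
#' @param sim a `cpf_sim` run with `trace = TRUE`.
#' @param params parameter list.
#' @return Data frame of grid cells (`row`, `col`, 1-based) of every fishing
#'   event during the rearing phase.
#' @export
fishing_locations <- function(sim, params = cpf_params()) {
  if (is.null(sim$trace)) stop("run the simulation with trace = TRUE")
  tm <- sim$trace
  sel <- tm[, "event"] == 2 & tm[, "phase"] == 2
  data.frame(row = pmin(floor(tm[sel, "y"] / params$cell_km) + 1,
                        params$grid_n),
             col = pmin(floor(tm[sel, "x"] / params$cell_km) + 1,
                        params$grid_n))
}
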