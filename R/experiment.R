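#' The full factorial design grid
#'
#' Enumerates every combination of aggregation, abundance, distance, body
#' length and memory type, each to be crossed with `n_maps` map replicates
#' and `n_seals` seal replicates.
#'
#' @param n_maps map replicates per condition.
#' @param n_seals seal replicates per map.
#' @param params parameter list.
#' @return A data frame of conditions with attribute `n_runs`, the total
#'   number of simulations the design implies.
#' @examples
#' g <- design_grid()
#' attr(g, "n_runs")  # 1,440,000
#' @export
design_grid <- function(n_maps = 10L, n_seals = 50L, params = cpf_params()) {
  g <- expand.grid(aggreg = params$aggreg_levels,
                   abund = params$abund_levels,
                   dist = params$dist_levels,
                   length = params$lengths,
                   mem = c(0L, 1L))
  attr(g, "n_runs") <- nrow(g) * n_maps * n_seals
  attr(g, "n_maps") <- as.integer(n_maps)
  attr(g, "n_seals") <- as.integer(n_seals)
  g
}

#' Run all replicates of one design condition
#'
#' Generates `n_maps` landscape replicates of the condition and runs
#' `n_seals` females on each; every run gets a deterministic sub-seed derived
#' from `seed`, so results are reproducible and independent of execution
#' order.
#'
#' @param aggreg,abund,dist landscape factors.
#' @param length,mem female factors.
#' @param n_maps,n_seals replicate counts.
#' @param seed master seed of the condition.
#' @param params parameter list.
#' @return Data frame with one row per run: replicate indices, survival
#'   flags, final masses, energy spent and the trip summaries of
#'   [trip_summary()].
#' @export
run_condition <- function(aggreg = 3, abund = 180, dist = 150, length = 115,
                          mem = 1L, n_maps = 10L, n_seals = 50L, seed = 1L,
                          params = cpf_params()) {
  out <- vector("list", n_maps * n_seals)
  k <- 0L
  for (im in seq_len(n_maps)) {
    map <- generate_resource_map(aggreg, abund, dist, rep_map = im,
                                 seed = derive_seed(seed, 1L, im),
                                 params = params)
    for (is in seq_len(n_seals)) {
      sim <- run_simulation(map, length = length, mem = mem,
                            seed = derive_seed(seed, 2L, im, is),
                            params = params)
      k <- k + 1L
      out[[k]] <- cbind(
        data.frame(aggreg = aggreg, abund = abund, dist = dist,
                   length = length, mem = mem, rep_map = im, rep = is,
                   female_survived = sim$female_survived,
                   pup_survived = sim$pup_survived,
                   final_mass_female = sim$final_mass_female,
                   final_mass_pup = sim$final_mass_pup,
                   e_spent = sim$total_energy_spent),
        trip_summary(sim))
    }
  }
  do.call(rbind, out)
}

#' Summarise the runs of one condition
#'
#' Statistics are computed per map replicate first (mortalities over all
#' runs; behavioural summaries over the females that completed their rearing
#' period; pup masses over surviving pups) and then averaged across map
#' replicates (mean and SD).
#'
#' @param runs the per-run data frame of [run_condition()].
#' @return One-row data frame with `d_f`, `d_p`, `sp`, survivor-filtered
#'   behavioural means (`mean_d_trip`, `mean_t_trip`, `nbr_trip`,
#'   `nbr_fishing`, `fish_per_trip`, `mean_e_fish`), final masses, mean
#'   energy spent, and the across-map SDs of the headline quantities.
#' @export
summarize_condition <- function(runs) {
  per_map <- lapply(split(runs, runs$rep_map), function(d) {
    surv_f <- d[d$female_survived, , drop = FALSE]
    surv_p <- d[d$pup_survived, , drop = FALSE]
    data.frame(
      d_f = mean(!d$female_survived),
      d_p = mean(!d$pup_survived),
      sp = pair_success(mean(!d$female_survived), mean(!d$pup_survived)),
      mean_d_trip = if (nrow(surv_f)) mean(surv_f$mean_d_trip, na.rm = TRUE)
        else NA_real_,
      mean_t_trip = if (nrow(surv_f)) mean(surv_f$mean_t_trip, na.rm = TRUE)
        else NA_real_,
      nbr_trip = if (nrow(surv_f)) mean(surv_f$n_trips) else NA_real_,
      nbr_fishing = if (nrow(surv_f)) mean(surv_f$n_fishing) else NA_real_,
      fish_per_trip = if (nrow(surv_f))
        mean(surv_f$n_fishing / pmax(surv_f$n_trips, 1)) else NA_real_,
      mean_e_fish = if (nrow(surv_f)) mean(surv_f$mean_e_fish, na.rm = TRUE)
        else NA_real_,
      mass_female = if (nrow(surv_f)) mean(surv_f$final_mass_female)
        else NA_real_,
      mass_pup = if (nrow(surv_p)) mean(surv_p$final_mass_pup) else NA_real_,
      e_spent = mean(d$e_spent))
  })
  pm <- do.call(rbind, per_map)
  means <- colMeans(pm, na.rm = TRUE)
  # the reported pair success is recomputable from the reported mortalities
  means[["sp"]] <- pair_success(means[["d_f"]], means[["d_p"]])
  sds <- vapply(pm, function(col) sd(col[!is.na(col)]), numeric(1))
  out <- as.data.frame(as.list(means))
  out$sd_d_trip <- sds[["mean_d_trip"]]
  out$sd_t_trip <- sds[["mean_t_trip"]]
  out$sd_sp <- sds[["sp"]]
  out$sd_mass_pup <- sds[["mass_pup"]]
  out$sd_mass_female <- sds[["mass_female"]]
  out$n_runs <- nrow(runs)
  out
}

#' Run a (possibly reduced) factorial design
#'
#' @param grid data frame of conditions, e.g. from [design_grid()] or a
#'   subset of it.
#' @param n_maps,n_seals replicate counts per condition.
#' @param seed master seed.
#' @param params parameter list.
#' @param verbose print progress.
#' @return Data frame with one summarised row per condition (the columns of
#'   [summarize_condition()] bound to the condition factors).
#' @export
run_design <- function(grid, n_maps = 10L, n_seals = 50L, seed = 1L,
                       params = cpf_params(), verbose = FALSE) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (verbose)
      message(sprintf("condition %d/%d: aggreg %s abund %s dist %s len %s mem %s",
                      i, nrow(grid), g$aggreg, g$abund, g$dist, g$length,
                      g$mem))
    runs <- run_condition(g$aggreg, g$abund, g$dist, g$length, g$mem,
                          n_maps, n_seals,
                          seed = derive_seed(seed, 3L, g$aggreg, g$abund,
                                             g$dist, g$length, g$mem),
                          params = params)
    rows[[i]] <- cbind(g, summarize_condition(runs), row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Cost/benefit ratio of a condition
#'
#' `R = E / SP`: mean total energy spent over the rearing period divided by
#' the success of the female-pup pair. `SP = 0` yields `Inf` (no finite cost
#' buys success).
#'
#' @param total_energy vector of per-run total energies spent (MJ).
#' @param sp pair success in \[0, 1\].
#' @return R in MJ.
#' @export
cost_benefit <- function(total_energy, sp) {
  if (any(total_energy < 0)) stop("energies must be non-negative")
  if (sp < 0 || sp > 1) stop("sp must lie in [0, 1]")
  if (sp == 0) return(Inf)
  mean(total_energy) / sp
}

## R(l) per body length from run-level records
r_by_length_from_runs <- function(runs) {
  by_len <- split(runs, runs$length)
  data.frame(
    length = as.numeric(names(by_len)),
    r = vapply(by_len, function(d) {
      sp <- pair_success(mean(!d$female_survived), mean(!d$pup_survived))
      cost_benefit(d$e_spent, sp)
    }, numeric(1)),
    row.names = NULL)
}

## argmin over [85,145] of a smooth fit of R on length; degree 2 and 3
## candidates, keep the curve whose minimum is lower
curve_argmin <- function(lens, r, grid = seq(85, 145, by = 0.1)) {
  ok <- is.finite(r)
  if (sum(ok) < 3) return(NA_real_)
  best_min <- Inf; best_arg <- NA_real_
  for (deg in 2:3) {
    if (sum(ok) <= deg) next
    fit <- lm(r[ok] ~ poly(lens[ok], deg, raw = TRUE))
    pred <- cbind(1, outer(grid, seq_len(deg), `^`)) %*% coef(fit)
    i <- which.min(pred)
    if (pred[i] < best_min) { best_min <- pred[i]; best_arg <- grid[i] }
  }
  best_arg
}

#' Bootstrap estimate of the optimal body length
#'
#' For each body length, `R = E/SP` is computed from run-level records; a
#' smooth curve of R over length (quadratic and cubic candidates, keeping the
#' lower minimum) gives the optimal length as its argmin on \[85, 145\] cm.
#' The confidence interval is obtained by bootstrap: runs are resampled with
#' replacement within each length, the curve refitted and its argmin
#' recorded; the 2.5 and 97.5 percentiles of the argmins bound the interval.
#'
#' @param runs per-run data frame (needs columns `length`, `e_spent`,
#'   `female_survived`, `pup_survived`), e.g. rows of [run_condition()]
#'   stacked over lengths.
#' @param n_boot bootstrap resamples.
#' @return List of class `optimality_result`: `r_by_length` (data frame),
#'   `optimal_length`, `ci_low`, `ci_high`, and the vector of bootstrap
#'   argmins.
#' @export
bootstrap_optimum <- function(runs, n_boot = 1000L) {
  rb <- r_by_length_from_runs(runs)
  if (sum(is.finite(rb$r)) < 2)
    stop("need at least two lengths with finite R")
  opt <- curve_argmin(rb$length, rb$r)
  by_len <- split(seq_len(nrow(runs)), runs$length)
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(by_len, function(ii)
      ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
    rbb <- r_by_length_from_runs(runs[idx, , drop = FALSE])
    boots[b] <- curve_argmin(rbb$length, rbb$r)
  }
  boots_ok <- boots[is.finite(boots)]
  structure(list(r_by_length = rb, optimal_length = opt,
                 ci_low = unname(quantile(boots_ok, 0.025)),
                 ci_high = unname(quantile(boots_ok, 0.975)),
                 boot_argmins = boots),
            class = "optimality_result")
}

#' @export
print.optimality_result <- function(x, ...) {
  cat("optimal body length:", round(x$optimal_length, 2), "cm  (95% CI",
      round(x$ci_low, 2), "-", round(x$ci_high, 2), ")\n")
  print(x$r_by_length, row.names = FALSE)
  invisible(x)
}

#' Optimal body length versus distance to the resource
#'
#' Least-squares line through the (distance, optimal length) pairs. The slope
#' is the ratio of the rate of body-length change to the rate of
#' resource-distance change; multiplied by the speed at which the foraging
#' grounds shift (km per year) it predicts the body-length drift (cm per
#' year) needed to keep the cost/benefit ratio optimal.
#'
#' @param optima data frame with columns `dist` (km) and `optimal_length`
#'   (cm); at least three distances.
#' @param shift_km_per_year speed of the foraging-ground shift.
#' @return List with `slope` (cm per km), `intercept`, `d0`/`l0` (the line
#'   re-anchored at the smallest distance) and `drift_cm_per_year`.
#' @export
optimal_length_regression <- function(optima, shift_km_per_year = 3) {
  optima <- optima[is.finite(optima$optimal_length), , drop = FALSE]
  if (nrow(optima) < 3) stop("need optima for at least three distances")
  fit <- lm(optimal_length ~ dist, data = optima)
  slope <- unname(coef(fit)[2])
  d0 <- min(optima$dist)
  list(slope = slope, intercept = unname(coef(fit)[1]),
       d0 = d0, l0 = unname(coef(fit)[1] + slope * d0),
       drift_cm_per_year = slope * shift_km_per_year,
       fit = fit)
}

#' Per-cell fishing frequencies of a set of females
#'
#' Runs `n_seals` traced simulations on one map and tallies the rearing-phase
#' fishing events per grid cell (the spatial fishing-pressure field).
#'
#' @param map a `resource_map`.
#' @param n_seals number of females.
#' @param length,mem female factors.
#' @param seed master seed.
#' @param params parameter list.
#' @return Data frame of fished cells: `row`, `col`, `n_events`, `abundance`.
#' @export
fishing_heatmap <- function(map, n_seals = 50L, length = 115, mem = 1L,
                            seed = 1L, params = cpf_params()) {
  counts <- matrix(0L, params$grid_n, params$grid_n)
  for (is in seq_len(n_seals)) {
    sim <- run_simulation(map, length = length, mem = mem,
                          seed = derive_seed(seed, 4L, is), params = params,
                          trace = TRUE)
    loc <- fishing_locations(sim, params)
    for (i in seq_len(nrow(loc)))
      counts[loc$row[i], loc$col[i]] <- counts[loc$row[i], loc$col[i]] + 1L
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             n_events = counts[idx],
             abundance = map$values[idx])
}
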