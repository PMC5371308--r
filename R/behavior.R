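#' Probability of fishing in the current cell
#'
#' Logistic in the local prey abundance,
#' `exp(2 (a - th_t)) / (1 + exp(2 (a - th_t)))`, equal to 0.5 at the
#' threshold `th_t`. Fishing is impossible during the day (the prey is out of
#' reach), below the profitability floor of 1.5 map units, and when the
#' female is at satiety (energy at its ceiling).
#'
#' @param abundance local prey abundance, map units (>= 0).
#' @param th_t threshold abundance at which the probability is 0.5.
#' @param is_night logical; fishing only happens at night.
#' @param at_satiety logical; `TRUE` when body energy has reached `e_max`.
#' @param params parameter list.
#' @return Probability in \[0, 1\].
#' @export
p_fishing <- function(abundance, th_t, is_night = TRUE, at_satiety = FALSE,
                      params = cpf_params()) {
  if (any(abundance < 0)) stop("abundance must be non-negative")
  p <- plogis(2 * (abundance - th_t))
  p[!is_night | at_satiety | abundance < params$min_fish_abund] <- 0
  p
}

#' Condition-dependent fishing threshold
#'
#' The abundance at which the probability of fishing is one half rises with
#' the female's condition: a female at her lethal energy floor fishes in any
#' profitable cell (`th_t` = 1.5 map units), while a female at the satiety
#' ceiling only accepts cells at least as rich as the average non-zero
#' environment (`th_t` = AvgEnv). In between, `th_t` interpolates in the
#' energy ratio `e_seal / e_min` through a convex map (`th_exponent` < 1):
#' females remain selective for rich cells until their reserves run low.
#'
#' @param avg_env mean abundance of the non-zero environment, map units.
#' @param e_ratio current energy over the lethal floor, `e_seal / e_min`.
#' @param params parameter list.
#' @return Threshold abundance in map units.
#' @export
compute_th_t <- function(avg_env, e_ratio, params = cpf_params()) {
  if (any(avg_env <= 0)) stop("avg_env must be positive")
  frac <- pmin(pmax((e_ratio - 1) / (params$thr_ceiling - 1), 0), 1)
  frac <- frac^params$th_exponent
  pmax(params$min_fish_abund,
       params$min_fish_abund + frac * (avg_env - params$min_fish_abund))
}

#' One turning step of the correlated random walk
#'
#' Adds a zero-mean Gaussian turning angle to the current heading. The
#' turning-angle spread is calibrated so successive hourly headings have a
#' lag-1 autocorrelation (mean cosine of the turn) of about 0.30, with
#' essentially no correlation at wider lags.
#'
#' @param heading current heading in radians.
#' @param params parameter list; `crw_turn_sd` is the turning sd in radians.
#' @return New heading in radians, wrapped to (-pi, pi\].
#' @export
crw_step <- function(heading, params = cpf_params()) {
  wrap_angle(heading + rnorm(length(heading), 0, params$crw_turn_sd))
}

wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Bearing between two points
#'
#' @param x0,y0 origin (km).
#' @param x1,y1 destination (km).
#' @return Heading in radians (atan2 convention: 0 = +x, pi/2 = +y).
#' @export
bearing <- function(x0, y0, x1, y1) atan2(y1 - y0, x1 - x0)

#' Choose the next heading
#'
#' Implements the three movement modes of a female at sea:
#' \describe{
#'   \item{transit}{straight towards a memorised target cell,}
#'   \item{search}{a correlated random walk, pulled towards the direction of
#'     a sensed positive abundance gradient between the last two distinct
#'     visited cells (circular weighted mean with weight `grad_weight`),}
#'   \item{naive}{uniform random heading (first hour of the prenatal period,
#'     or a departure with no usable memory).}
#' }
#'
#' @param mode one of `"transit"`, `"search"`, `"naive"`.
#' @param heading current heading (radians); used by `"search"`.
#' @param target_bearing bearing to the memorised cell (radians); used by
#'   `"transit"`.
#' @param gradient_bearing bearing of a sensed positive abundance gradient,
#'   or `NA` when no gradient (or a tie) was sensed.
#' @param params parameter list.
#' @return New heading in radians.
#' @export
choose_heading <- function(mode = c("search", "transit", "naive"),
                           heading = 0, target_bearing = NA,
                           gradient_bearing = NA, params = cpf_params()) {
  mode <- match.arg(mode)
  if (mode == "naive") return(runif(1, -pi, pi))
  if (mode == "transit") {
    if (is.na(target_bearing)) stop("transit mode needs a target bearing")
    return(wrap_angle(target_bearing))
  }
  h <- crw_step(heading, params)
  if (!is.na(gradient_bearing)) {
    w <- params$grad_weight
    h <- atan2((1 - w) * sin(h) + w * sin(gradient_bearing),
               (1 - w) * cos(h) + w * cos(gradient_bearing))
  }
  h
}

#' Probability of ending the trip and returning to the colony
#'
#' Combines an energy-margin term and a trip-duration ramp:
#' `p = min(1, exp(-k * max(e_frac - ewb_frac, 0)) + min(ts_frac, 1)^gamma)`.
#' The probability is 1 as soon as the current energy fraction no longer
#' exceeds the fraction needed to return and spend two days ashore
#' (`e_frac <= ewb_frac`), or when the trip has reached its maximal duration
#' (`ts_frac >= 1`). It is non-increasing in `e_frac` and non-decreasing in
#' `ewb_frac` and `ts_frac`.
#'
#' @param e_frac current energy over maximal energy, `e_seal / e_max`.
#' @param ewb_frac energy needed to return over maximal energy: the
#'   female's intrinsic requirement (her lethal floor) plus the travel back
#'   and, when a pup waits ashore, two shore days.
#' @param ts_frac time already at sea over the maximal trip duration.
#' @param params parameter list (`return_k`, `return_gamma`).
#' @return Probability in \[0, 1\].
#' @export
p_return <- function(e_frac, ewb_frac, ts_frac, params = cpf_params()) {
  if (any(e_frac < 0) || any(ewb_frac < 0) || any(ts_frac < 0))
    stop("inputs must be non-negative")
  margin <- pmax(e_frac - ewb_frac, 0)
  pmin(1, exp(-params$return_k * margin) +
         pmin(ts_frac, 1)^params$return_gamma)
}

#' Scheduled departure hour for a new trip
#'
#' A female leaves at a consistent hour, constrained to reach her memorised
#' feeding area during the night. With no usable target the default
#' departure hour (17:00) applies; with a target at distance `d` km the
#' departure hour is the feasible hour closest to 17:00 for which arrival
#' (after `ceiling(d / speed)` hours of travel) falls within the night.
#'
#' @param target_km distance to the memorised cell (km), or `NA`.
#' @param params parameter list.
#' @return Integer hour of day (0-23).
#' @export
departure_hour_for <- function(target_km = NA, params = cpf_params()) {
  if (is.na(target_km)) return(as.integer(params$departure_hour))
  travel <- ceiling(target_km / params$step_km)
  hours <- 0:23
  arr <- (hours + travel) %% 24
  night <- arr >= params$night_start | arr < (params$night_start +
                                                params$night_len) %% 24
  feas <- hours[night]
  dd <- abs(feas - params$departure_hour)
  dd <- pmin(dd, 24 - dd)
  as.integer(feas[which.min(dd)])
}

#' Stay ashore or leave for a new trip
#'
#' A female stays ashore for at least the mean time ashore (two days) and
#' then departs at the scheduled hour of day (see [departure_hour_for()]).
#'
#' @param hour_of_day current hour of day (0-23).
#' @param t_ashore hours already spent ashore this visit.
#' @param target_km distance to the memorised target (km), or `NA`.
#' @param params parameter list.
#' @return `"leave"` or `"stay"`.
#' @export
decide_departure <- function(hour_of_day, t_ashore, target_km = NA,
                             params = cpf_params()) {
  if (t_ashore < params$mta_h) return("stay")
  if (hour_of_day == departure_hour_for(target_km, params)) "leave" else "stay"
}

#' Update the best-cell memory
#'
#' The memorised reference cell is replaced only by a strictly richer cell.
#'
#' @param memory list with `best_x`, `best_y`, `best_abundance`,
#'   `last_trip_gain_rate`.
#' @param x,y centre coordinates of the visited cell (km).
#' @param abundance abundance of the visited cell (map units).
#' @return The updated memory list.
#' @export
update_memory <- function(memory, x, y, abundance) {
  if (abundance > memory$best_abundance) {
    memory$best_x <- x
    memory$best_y <- y
    memory$best_abundance <- abundance
  }
  memory
}

#' Fidelity to the memorised cell after a trip
#'
#' Saturating function of the realised gain rate of the previous trip,
#' `g / (g + g_half)` with `g = E_won / duration` (MJ h^-1). A failed trip
#' (no energy gained) gives fidelity 0, so the next departure heading is
#' random.
#'
#' @param gain_rate energy gained on the previous trip divided by its
#'   duration, MJ h^-1.
#' @param params parameter list (`g_half`).
#' @return Fidelity in \[0, 1).
#' @export
trip_fidelity <- function(gain_rate, params = cpf_params()) {
  g <- pmax(gain_rate, 0)
  g / (g + params$g_half)
}
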