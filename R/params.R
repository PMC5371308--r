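#' Model parameters
#'
#' Returns the full set of physiological, behavioural and landscape constants
#' used by the simulator, with any element overridable by name. Values mirror
#' field estimates for lactating Antarctic fur seal females and their pups at
#' the Kerguelen archipelago; the handful of free constants (milk-transfer
#' rate, return-decision shape, landscape calibration) were calibrated once
#' against published colony-level outputs and are frozen here.
#'
#' Units: energies MJ, masses kg, distances km, time steps 1 h, abundances in
#' map units (1 map unit = 36.667 g of catchable prey per fishing hour, so
#' the 1.5 map-unit profitability floor corresponds to about 55 g h^-1).
#'
#' @param ... named overrides of any default element.
#' @return A named list of parameters.
#' @examples
#' p <- cpf_params(t_max_trip_h = 240)
#' p$fmr_sea
#' @export
cpf_params <- function(...) {
  p <- list(
    ## -- grid ------------------------------------------------------------
    grid_n        = 100L,   # cells per side
    cell_km       = 10,     # cell edge, km
    plateau_km    = 50,     # unsuitable shelf around the island
    max_range_km  = 500,    # outer limit of the prey field
    ## -- landscape generator (thresholded Gaussian random field) ---------
    offset_per_aggreg = 0.095, # standard-normal offset subtracted before
                            # truncation at zero, per aggregation unit: higher
                            # aggregation concentrates the same resource into
                            # fewer, larger blobs
    scale_per_aggreg = 0.74,# smoothing kernel sd (cells) per aggregation unit
    field_power   = 2,      # exponent applied to the truncated field:
                            # controls how strongly prey concentrate in cores
    patch_thr_factor = 1.5, # patch statistics count cells above this
                            # multiple of the map's mean non-zero abundance
    ring_taper    = 0.85,   # fractional amplitude decline from the distance
                            # to the resource out to the range limit
    abund_levels  = c(90, 180, 270, 360),         # g h^-1 over non-zero cells
    aggreg_levels = c(0, 1, 2, 3, 4, 6, 8, 10),
    dist_levels   = seq(100, 500, by = 50),       # km
    ## -- female physiology ------------------------------------------------
    lengths        = c(85, 100, 115, 130, 145),   # cm
    mass_slope     = 0.5246,  # kg cm^-1, length-mass regression
    mass_intercept = -29.595, # kg
    econtent_seal  = 10.59,   # MJ kg^-1
    fmr_sea        = 6.09,    # W kg^-1 at sea
    ashore_met_frac = 0.3,    # resting metabolism ashore, fraction of at-sea
    speed_ms       = 2.11,    # horizontal swimming speed, m s^-1
    drag_85        = 0.041,   # MJ km^-1 of travel for an 85 cm female
    drag_ref_length = 85,     # cm; drag scales with (length/85)^2
    satiation_frac = 0.07,    # max intake per feeding, fraction of the
                              # energy held at the end of the former night
    emax_factor    = 1.07,    # ceiling on body energy vs mass at last dawn
    ## -- prey intake -------------------------------------------------------
    g_per_unit     = 55 / 1.5, # g of prey per map unit per fishing hour
    kcal_per_g     = 4,        # fish mass to energy
    kj_per_kcal    = 4.184,
    min_fish_abund = 1.5,      # map units; below this fishing not profitable
    ## -- pup ---------------------------------------------------------------
    econtent_pup   = 8.24,   # MJ kg^-1
    pup_init_mass  = 5.5,    # kg at birth
    pup_max_mass   = 18,     # kg
    perinatal_gain = 1.5,    # kg gained over the perinatal fast
    pup_loss_per_hour = 0.0012, # fraction of energy lost per starving hour
    milk_rate      = 0.0013, # fraction of the female spendable surplus
                             # (above her lethal floor) given per shore hour;
                             # calibrated against weaning masses
    ## -- mortality ---------------------------------------------------------
    lethal_pct_female = 70,  # % of reference energy at which P(death) = 0.5
    lethal_pct_pup    = 56,
    mort_sd_pct       = 0.5, # sd of the threshold, percentage points
    ## -- behaviour ---------------------------------------------------------
    night_start    = 22L,    # hour of day; night covers 22:00-06:00 (8 h)
    night_len      = 8L,
    departure_hour = 17L,    # preferred departure hour when unconstrained
    mta_h          = 48,     # minimum/mean time ashore between trips, h
    prenatal_ashore_h = 12,  # shorter rests between prospection trips
                             # (no pup to suckle yet)
    t_max_trip_h   = 168,    # upper bound on trip duration (7 days)
    return_k       = 100,    # steepness of the energy-margin return term
    emergency_frac = 0.78,   # ashore: depart early once energy falls below
                             # this fraction of the trip-start reference
    return_gamma   = 4,      # exponent of the trip-duration return ramp
    satiety_return_frac = 0.96, # a female this close to her storage ceiling
                             # gains nothing by staying at sea and heads home
    th_exponent    = 0.25,   # convexity of the condition-to-pickiness map:
                             # females stay selective until reserves are low
    crw_turn_sd    = sqrt(-2 * log(0.302)), # rad; lag-1 heading autocorr 0.302
    outbound_turn_sd = 0.15, # rad; commuting legs are nearly straight
    grad_weight    = 0.8,    # pull of a sensed abundance gradient on heading
    g_half         = 0.05,   # MJ h^-1; half-saturation of trip-gain fidelity
    mem_dist_discount = 0.036, # map units per km: the remembered reference
                             # cell maximises abundance net of travel cost
    prospect_th_factor = 1.5, # prospecting females only accept cells this
                             # many times richer than the average environment
    ## -- schedule ----------------------------------------------------------
    prenatal_days  = 15,
    perinatal_days = c(5, 7), # uniform draw on {5,6,7}
    t_rearing_h    = 2880     # 120 days
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  ## derived quantities
  p$step_km    <- p$speed_ms * 3600 / 1000          # km per moving hour
  p$met_mj_kg  <- p$fmr_sea * 3600 / 1e6            # MJ kg^-1 h^-1 at sea
  p$mj_per_unit <- p$g_per_unit * p$kcal_per_g * p$kj_per_kcal / 1000
  p$thr_ceiling <- p$emax_factor / (p$lethal_pct_female / 100)
  p
}

#' Derive a reproducible sub-seed
#'
#' Hashes a master seed with any number of integer indices (map replicate,
#' seal replicate, design-cell coordinates, ...) into a deterministic seed
#' below `.Machine$integer.max`, so large experiments stay reproducible and
#' independent of execution order.
#'
#' @param master master seed (integer).
#' @param ... integer indices identifying the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i) * 9973 + 1) %% 2147483647
  as.integer(s)
}
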