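#' Hourly metabolic cost at sea
#'
#' Field metabolic rate of 6.09 W kg^-1 converted to MJ per hour:
#' 0.021924 MJ kg^-1 h^-1.
#'
#' @param w_seal female mass in kg.
#' @param params parameter list.
#' @return Energy spent in MJ over one hour at sea.
#' @export
metabolic_cost_hour <- function(w_seal, params = cpf_params()) {
  if (any(w_seal <= 0)) stop("mass must be positive")
  params$met_mj_kg * w_seal
}

#' Energy gained during one fishing hour
#'
#' Catch is proportional to local prey abundance (1 map unit = 36.667 g h^-1;
#' 4 kcal per g of fish). Intake during a single feeding cannot exceed 7% of
#' the energy the female held at the end of the former night (satiation), and
#' body energy can never exceed the current ceiling `e_max`.
#'
#' @param abundance local prey abundance in map units (>= 0).
#' @param e_seal current female energy, MJ.
#' @param e_max current maximal energy, MJ.
#' @param e_former_night energy at the end of the former night, MJ (satiation
#'   reference).
#' @param params parameter list.
#' @return Realised energy gain in MJ.
#' @export
fishing_gain <- function(abundance, e_seal, e_max, e_former_night,
                         params = cpf_params()) {
  if (any(abundance < 0)) stop("abundance must be non-negative")
  raw <- abundance * params$mj_per_unit
  min(raw, params$satiation_frac * e_former_night, max(e_max - e_seal, 0))
}

#' The female's maximal-energy ceiling
#'
#' Body energy can never exceed 1.07 x a reference mass x energy content.
#' In the simulation the ceiling is a fixed storage capacity anchored at the
#' female's initial mass; the satiation reference (the energy held at the
#' end of the former night) is reset at every dawn.
#'
#' @param w_end_of_night reference mass, kg.
#' @param params parameter list.
#' @return The ceiling `e_max` in MJ.
#' @export
update_emax <- function(w_end_of_night, params = cpf_params()) {
  params$emax_factor * w_end_of_night * params$econtent_seal
}

#' One hour of pup fasting
#'
#' A starving pup loses 0.12% of its energy per hour (about 2.8% per day).
#'
#' @param pup a `pup_state`.
#' @param params parameter list.
#' @return The updated `pup_state`.
#' @export
pup_starve_hour <- function(pup, params = cpf_params()) {
  pup$e_pup <- pup$e_pup * (1 - params$pup_loss_per_hour)
  pup$w_pup <- pup$e_pup / params$econtent_pup
  pup
}

#' One hour of suckling ashore
#'
#' Milk energy transferred per shore hour is a fixed fraction (`milk_rate`)
#' of the female's spendable surplus above her lethal floor; the transfer is
#' truncated so the pup never exceeds its maximal mass (18 kg) and the female
#' never goes below zero energy. A female with no surplus transfers nothing.
#'
#' @param female a `female_state`.
#' @param pup a `pup_state`.
#' @param params parameter list.
#' @return List with updated `female`, `pup` and the realised `transfer` (MJ).
#' @export
suckle_hour <- function(female, pup, params = cpf_params()) {
  surplus <- max(female$e_seal - female$e_min, 0)
  transfer <- params$milk_rate * surplus
  transfer <- min(transfer,
                  max(params$pup_max_mass * params$econtent_pup - pup$e_pup, 0),
                  female$e_seal)
  female$e_seal <- female$e_seal - transfer
  female$w_seal <- female$e_seal / params$econtent_seal
  pup$e_pup <- pup$e_pup + transfer
  pup$w_pup <- pup$e_pup / params$econtent_pup
  female$t_suckling <- female$t_suckling + 1
  list(female = female, pup = pup, transfer = transfer)
}
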