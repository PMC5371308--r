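#' Hourly probability of death from energy depletion
#'
#' Death risk depends on the percentage of a reference energy still held.
#' The probability is a normal CDF of that percentage, centred on the lethal
#' fraction (70% for females, 56% for pups) with a spread of 2 percentage
#' points: exactly 0.5 at the lethal fraction, essentially 0 near 100% and
#' essentially 1 well below the threshold. One Bernoulli draw is made per
#' simulated hour. The reference is the initial (departure) energy for the
#' female and the highest post-suckling energy for the pup.
#'
#' @param current_energy current energy, MJ.
#' @param reference_energy reference energy, MJ (> 0).
#' @param who `"female"` or `"pup"`.
#' @param params parameter list.
#' @return Probability of dying during the hour.
#' @examples
#' p_death(70, 100, "female")  # 0.5
#' p_death(56, 100, "pup")     # 0.5
#' @export
p_death <- function(current_energy, reference_energy,
                    who = c("female", "pup"), params = cpf_params()) {
  who <- match.arg(who)
  if (any(reference_energy <= 0)) stop("reference energy must be positive")
  lethal <- if (who == "female") params$lethal_pct_female else
    params$lethal_pct_pup
  pct <- 100 * current_energy / reference_energy
  pnorm((lethal - pct) / params$mort_sd_pct)
}

#' Success of the female-pup pair
#'
#' `SP = (1 - D_f) (1 - D_p)`: the probability that both members of the pair
#' survive the rearing period, given the two death probabilities.
#'
#' @param d_f probability of female death in \[0, 1\].
#' @param d_p probability of pup death in \[0, 1\].
#' @return SP in \[0, 1\].
#' @export
pair_success <- function(d_f, d_p) {
  if (any(d_f < 0 | d_f > 1) || any(d_p < 0 | d_p > 1))
    stop("death probabilities must lie in [0, 1]")
  (1 - d_f) * (1 - d_p)
}
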