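#' Simulation configuration for a synthetic SCNP cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' Defaults encode the study conditions the package emulates: an elderly AML
#' cohort with a 72% responder (CR/CRi) rate among non-TRM patients, a 15%
#' treatment-related-mortality rate, ~15% secondary AML, bone-marrow and
#' peripheral-blood sample availability of 60% and 76%, and a latent
#' per-patient chemosensitivity in `[0, 1]` that (i) drives the induction
#' outcome through a logistic link and (ii) scales the apoptosis response
#' (cleaved-PARP up-shift, CD34 down-shift, viability loss) of blasts exposed
#' to cytarabine + daunorubicin for 24 hours in vitro.
#'
#' @param n_patients cohort size.
#' @param response_rate target responder fraction among CR/CRi/RD patients.
#' @param trm_rate probability of a TRM outcome, independent of the latent
#'   chemosensitivity (the assay measures blast chemosensitivity, not
#'   comorbidity).
#' @param cri_frac fraction of responders coded CRi rather than CR.
#' @param secondary_frac fraction of secondary (post-MDS) AML.
#' @param tissue_prob named probabilities of BM and PB sample availability;
#'   a patient with neither draw is assigned BM so that every patient has at
#'   least one tissue.
#' @param outcome_slope slope of the logistic link from latent
#'   chemosensitivity to response; the intercept is solved numerically so the
#'   expected responder rate equals `response_rate`.
#' @param cyto_effect log-odds shift of response for better (+) and poor (-)
#'   true cytogenetic risk.
#' @param effect_cparp,effect_cd34 natural-log intensity shift of blast cPARP
#'   (up) and CD34 (down) in the 24 h AraC+Dauno well at latent
#'   chemosensitivity 1 (shifts scale linearly in the latent value).
#' @param effect_death added dead-cell fraction in the 24 h AraC+Dauno well at
#'   latent chemosensitivity 1. Deliberately small by default: simple
#'   viability loss at 24 h carries little outcome information (membrane
#'   permeability lags cPARP cleavage), so the viability-dye node is a weak
#'   predictor while the cPARP/CD34 nodes carry the planted signal.
#' @param pb_bm_discordance mixing weight in `[0, 1]` replacing the latent
#'   chemosensitivity of secondary-AML PB samples with an independent draw
#'   (0 = PB identical to BM biology).
#' @param node_noise_cparp,node_noise_cd34 sd of the per-patient biological
#'   noise with which each apoptosis node measures the latent
#'   chemosensitivity. The cPARP execution marker is the more direct (less
#'   noisy) readout; CD34-subset depletion is an indirect composite, hence
#'   noisier.
#' @param node_noise_weak sd of the (independent) biological noise of the
#'   secondary drug exposures (AraC alone, etoposide), whose weaker
#'   apoptosis induction yields a lower signal-to-noise readout.
#' @param mean_events Poisson mean of events acquired per well.
#' @param noise_patient sd of per-patient-per-channel log-intensity offsets.
#' @param plate_gain_sd sd of per-plate log-normal channel gains (removable by
#'   bead calibration).
#' @param plate_size patient-tissue units per plate.
#' @param debris_frac,dead_frac baseline debris and dead-cell fractions per
#'   well.
#' @param missing_cyto_frac fraction of patients whose cytogenetic risk is
#'   recorded as unknown.
#' @param seed RNG seed recorded in all outputs.
#' @return an object of class `scnp_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
scnp_sim_config <- function(n_patients = 100L,
                            response_rate = 0.72,
                            trm_rate = 0.15,
                            cri_frac = 0.30,
                            secondary_frac = 0.15,
                            tissue_prob = c(BM = 0.60, PB = 0.76),
                            outcome_slope = 6,
                            cyto_effect = 0.6,
                            effect_cparp = 1.2,
                            effect_cd34 = 1.0,
                            effect_death = 0.05,
                            node_noise_cparp = 0.10,
                            node_noise_cd34 = 0.25,
                            node_noise_weak = 0.35,
                            pb_bm_discordance = 0.8,
                            mean_events = 10000,
                            noise_patient = 0.15,
                            plate_gain_sd = 0.10,
                            plate_size = 28L,
                            debris_frac = 0.05,
                            dead_frac = 0.05,
                            missing_cyto_frac = 0.20,
                            seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive integer", call. = FALSE)
  for (nm in c("response_rate", "trm_rate", "cri_frac", "secondary_frac",
               "pb_bm_discordance", "debris_frac", "dead_frac",
               "missing_cyto_frac"))
    check_prob(get(nm), nm)
  check_prob(tissue_prob, "tissue_prob")
  if (!all(c("BM", "PB") %in% names(tissue_prob)))
    stop("tissue_prob must be named with BM and PB", call. = FALSE)
  for (nm in c("outcome_slope", "cyto_effect", "effect_cparp", "effect_cd34",
               "effect_death", "node_noise_cparp", "node_noise_cd34",
               "node_noise_weak", "noise_patient", "plate_gain_sd"))
    if (!is.finite(get(nm))) stop(nm, " must be finite", call. = FALSE)
  if (mean_events <= 0) stop("mean_events must be positive", call. = FALSE)
  if (plate_size < 1) stop("plate_size must be positive", call. = FALSE)
  cfg <- list(n_patients = as.integer(n_patients),
              response_rate = response_rate, trm_rate = trm_rate,
              cri_frac = cri_frac, secondary_frac = secondary_frac,
              tissue_prob = tissue_prob, outcome_slope = outcome_slope,
              cyto_effect = cyto_effect, effect_cparp = effect_cparp,
              effect_cd34 = effect_cd34, effect_death = effect_death,
              pb_bm_discordance = pb_bm_discordance,
              node_noise_cparp = node_noise_cparp,
              node_noise_cd34 = node_noise_cd34,
              node_noise_weak = node_noise_weak,
              mean_events = mean_events, noise_patient = noise_patient,
              plate_gain_sd = plate_gain_sd, plate_size = as.integer(plate_size),
              debris_frac = debris_frac, dead_frac = dead_frac,
              missing_cyto_frac = missing_cyto_frac, seed = as.integer(seed))
  class(cfg) <- "scnp_sim_config"
  cfg
}

#' @export
print.scnp_sim_config <- function(x, ...) {
  cat("SCNP simulation config:", x$n_patients, "patients, seed", x$seed, "\n")
  cat("  response rate", x$response_rate, "| TRM", x$trm_rate,
      "| secondary AML", x$secondary_frac, "\n")
  cat("  apoptosis effects: cPARP +", x$effect_cparp, ", CD34 -",
      x$effect_cd34, ", death +", x$effect_death, "(log scale, x latent)\n")
  cat("  events/well ~Poisson(", x$mean_events, "), plate gain sd ",
      x$plate_gain_sd, "\n", sep = "")
  invisible(x)
}
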