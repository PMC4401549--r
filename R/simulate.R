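# Synthetic SCNP cohort simulator: patients, plates, wells, single-cell events
# and rainbow-bead plates with the statistical structure the downstream
# analysis assumes. Stands in for the study's private clinical samples.

# fluorescence channels the simulator can generate (scatter handled separately)
FLUOR_CHANNELS <- c("AquaAmine", "CD45", "CD34", "cPARP",
                    "pAKT", "pERK", "pS6", "pSTAT1", "pSTAT3", "pSTAT5", "pCREB")
READOUT_CHANNELS <- c("pAKT", "pERK", "pS6", "pSTAT1", "pSTAT3", "pSTAT5", "pCREB")
CORE_CHANNELS <- c("FSC", "SSC", "AquaAmine", "CD45", "CD34", "cPARP")

# per-modulator signaling response amplitudes (natural-log shift of the
# readout in responsive blasts); apoptosis modulators are handled separately
MODULATOR_AMPLITUDE <- list(
  "FLT3L"  = c(pAKT = 0.9, pERK = 0.7, pS6 = 0.7),
  "PMA"    = c(pCREB = 1.2, pERK = 1.0),
  "IL-27"  = c(pSTAT1 = 0.6, pSTAT3 = 0.8, pSTAT5 = 0.7)
)
# scaling of the AraC+Dauno apoptosis effect for related drug exposures
APOPTOSIS_SCALE <- list("AraC+Dauno" = 1.0, "AraC" = 0.6, "etoposide" = 0.8)

#' Default signaling-node panel
#'
#' The (modulator, exposure time, readout, metric, target population) panel
#' exercised by the simulator and the classifier pipeline: the two locked
#' 24-hour apoptosis nodes (AraC+Dauno to cPARP and to CD34), related drug
#' exposures, short-term survival-pathway nodes on cPARP-negative (healthy)
#' blasts, basal metrics, the percent-healthy and CD34-phenotyping rows, and
#' the Amine Aqua viability-loss readout. Shipped as a YAML fixture in
#' `inst/extdata/node_panel.yaml`.
#'
#' @return data.frame with columns `modulator`, `time_hr`, `readout`,
#'   `metric`, `population`.
#' @export
default_node_panel <- function() {
  path <- system.file("extdata", "node_panel.yaml", package = "scnpdx")
  if (path == "") stop("node panel fixture not found")
  read_node_panel(path)
}

#' Read a signaling-node panel from YAML
#'
#' @param path YAML file with a top-level `nodes` list; each entry has
#'   `modulator`, `time_hr`, `readout`, `metric` and `population`.
#' @return data.frame as in [default_node_panel()].
#' @export
read_node_panel <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$nodes)) stop("panel YAML must contain a 'nodes' list")
  panel <- do.call(rbind, lapply(spec$nodes, function(nd) {
    data.frame(modulator = nd$modulator, time_hr = as.numeric(nd$time_hr),
               readout = nd$readout, metric = nd$metric,
               population = nd$population, stringsAsFactors = FALSE)
  }))
  key <- with(panel, paste(modulator, time_hr, readout, metric))
  if (anyDuplicated(key)) stop("duplicate (modulator, time, readout, metric) in panel")
  ok_pop <- panel$population %in% c("intact", "viable", "blast", "healthy_blast")
  if (!all(ok_pop)) stop("unknown population: ", panel$population[!ok_pop][1])
  panel
}

#' Construct a single-well event table
#'
#' @param data data.frame of per-event channel intensities (one column per
#'   channel, equal lengths, unique names, nonnegative values).
#' @param well_id,patient_id,tissue,modulator,time_hr,plate well metadata.
#' @param scale `"raw"` or `"ERF"`.
#' @return object of class `scnp_events`.
#' @export
scnp_events <- function(data, well_id, patient_id, tissue, modulator, time_hr,
                        plate = NA_integer_, scale = "raw") {
  stopifnot(is.data.frame(data))
  if (anyDuplicated(names(data))) stop("channel names must be unique")
  if (nrow(data) > 0 && any(vapply(data, function(col) any(col < 0), logical(1))))
    stop("raw intensities must be nonnegative")
  structure(list(data = data, well_id = well_id, patient_id = patient_id,
                 tissue = tissue, modulator = modulator, time_hr = time_hr,
                 plate = plate, scale = scale, n_events = nrow(data)),
            class = "scnp_events")
}

#' @export
print.scnp_events <- function(x, ...) {
  cat(sprintf("<scnp_events> %s: %s %s, %s @ %gh, %d events x %d channels [%s]\n",
              x$well_id, x$patient_id, x$tissue, x$modulator, x$time_hr,
              x$n_events, ncol(x$data), x$scale))
  invisible(x)
}

# lognormal draw helper: meanlog already includes patient offset and effects;
# plate gain multiplies the linear intensity
rln <- function(n, meanlog, sdlog, gain = 1) gain * stats::rlnorm(n, meanlog, sdlog)

#' Simulate one well of single-cell events
#'
#' Draws events from a four-component mixture (debris, dead cells,
#' lymphocytes, blasts) with the blast fraction tied to the patient's blast
#' percentage for the tissue. Channel intensities are lognormal per
#' subpopulation; the autofluorescence well carries no antibody or viability
#' dye signal. Modulated wells shift the relevant readout channel: 24-hour
#' AraC+Dauno exposure up-shifts blast cPARP, down-shifts blast CD34 and adds
#' dead cells in proportion to the patient's latent chemosensitivity, while
#' short-term modulators (FLT3L, PMA, IL-27) shift their phospho-readouts by
#' a patient responsiveness factor unrelated to outcome.
#'
#' Events are drawn from the current RNG stream: two calls from the same RNG
#' state yield identical tables.
#'
#' @param patient one-row data.frame from a simulated cohort (or a list) with
#'   at least `patient_id`, `bm_blast_pct`, `pb_blast_pct`; latent
#'   chemosensitivity and responsiveness are read from `latent` and
#'   `responsiveness` if present.
#' @param tissue `"BM"` or `"PB"`.
#' @param modulator modulator name (`"autofluorescence"`, `"unmodulated"`, a
#'   drug or a ligand).
#' @param time_hr exposure time in hours.
#' @param channels channel names to generate (must be known to the panel).
#' @param config an [scnp_sim_config()].
#' @param gains named per-channel plate gains for fluorescence channels
#'   (default 1).
#' @param offsets named per-channel patient log-intensity offsets (default 0).
#' @param n_events event count; by default drawn from
#'   `Poisson(config$mean_events)`.
#' @return `scnp_events` with a `"population"` attribute on `$data` carrying
#'   the simulator's ground-truth component labels.
#' @export
simulate_well <- function(patient, tissue, modulator, time_hr, channels,
                          config = scnp_sim_config(), gains = NULL,
                          offsets = NULL, n_events = NULL) {
  unknown <- setdiff(channels, c("FSC", "SSC", FLUOR_CHANNELS))
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  s <- patient$latent %||% 0
  # node-level biological noise; secondary drug exposures (AraC alone,
  # etoposide) are independent, noisier measurements of the same latent
  if (identical(modulator, "AraC+Dauno")) {
    s_cparp <- patient$latent_cparp %||% s
    s_cd34 <- patient$latent_cd34 %||% s
  } else {
    s_cparp <- patient$latent_cparp_weak %||% s
    s_cd34 <- patient$latent_cd34_weak %||% s
  }
  resp <- patient$responsiveness %||% 1
  blast_pct <- if (tissue == "BM") patient$bm_blast_pct else patient$pb_blast_pct
  if (is.null(n_events)) n_events <- stats::rpois(1L, config$mean_events)
  stained <- !identical(modulator, "autofluorescence")

  apo <- 0
  if (modulator %in% names(APOPTOSIS_SCALE) && time_hr >= 24)
    apo <- APOPTOSIS_SCALE[[modulator]]
  dead_frac <- min(config$dead_frac + apo * config$effect_death * s, 0.9)
  debris_frac <- config$debris_frac
  cell_frac <- max(1 - dead_frac - debris_frac, 0)
  probs <- c(debris = debris_frac, dead = dead_frac,
             lymphocyte = cell_frac * (1 - blast_pct / 100),
             blast = cell_frac * blast_pct / 100)
  pop <- factor(sample(names(probs), n_events, replace = TRUE, prob = probs),
                levels = names(probs))
  n_by <- table(pop)

  if (is.null(gains)) gains <- stats::setNames(rep(1, length(FLUOR_CHANNELS)),
                                               FLUOR_CHANNELS)
  if (is.null(offsets)) offsets <- stats::setNames(rep(0, length(FLUOR_CHANNELS)),
                                                   FLUOR_CHANNELS)
  amp <- if (stained && modulator %in% names(MODULATOR_AMPLITUDE))
    MODULATOR_AMPLITUDE[[modulator]] else numeric(0)

  # meanlog per (channel, population); natural-log scale
  mean_for <- function(ch, p) {
    off <- if (ch %in% FLUOR_CHANNELS) offsets[[ch]] else 0
    if (ch == "FSC") return(if (p == "debris") 9.0 else 10.0)
    if (ch == "SSC") return(switch(p, debris = 8.6, dead = 9.0,
                                   lymphocyte = 8.5, blast = 8.9))
    if (!stained) {
      base <- switch(ch, AquaAmine = 4.0, CD45 = 4.0, CD34 = 4.0,
                     cPARP = 4.2, 4.0)
      return(base + off)
    }
    m <- switch(ch,
      AquaAmine = switch(p, debris = 6.0, dead = 6.5, 4.0),
      CD45 = switch(p, debris = 5.0, dead = 6.0, lymphocyte = 8.3, blast = 6.3),
      CD34 = switch(p, debris = 4.5, dead = 5.0, lymphocyte = 4.2,
                    blast = 6.0 - apo * config$effect_cd34 * s_cd34),
      cPARP = switch(p, debris = 5.0, dead = 6.0, lymphocyte = 4.6,
                     blast = 4.6 + apo * config$effect_cparp * s_cparp),
      { # phospho readouts
        base <- switch(p, debris = 4.4, dead = 4.6, lymphocyte = 4.8, blast = 5.0)
        if (ch %in% names(amp))
          base <- base + amp[[ch]] * resp * switch(p, blast = 1, lymphocyte = 0.3, 0)
        base
      })
    m + off
  }
  sd_for <- function(ch, p) {
    if (ch == "FSC") return(if (p == "debris") 0.30 else 0.35)
    if (ch == "SSC") return(0.40)
    if (!stained) return(0.50)
    switch(ch, AquaAmine = if (p %in% c("dead", "debris")) 0.40 else 0.50,
           CD45 = if (p == "blast") 0.50 else 0.35,
           CD34 = 0.60, cPARP = 0.60, 0.50)
  }

  dat <- as.data.frame(lapply(stats::setNames(channels, channels), function(ch) {
    out <- numeric(n_events)
    g <- if (ch %in% FLUOR_CHANNELS) gains[[ch]] else 1
    for (p in names(probs)) {
      k <- n_by[[p]]
      if (k > 0) out[pop == p] <- rln(k, mean_for(ch, p), sd_for(ch, p), g)
    }
    out
  }))
  attr(dat, "population") <- pop
  scnp_events(dat,
              well_id = sprintf("%s_%s_%s_%gh", patient$patient_id, tissue,
                                gsub("[^A-Za-z0-9]", "", modulator), time_hr),
              patient_id = patient$patient_id, tissue = tissue,
              modulator = modulator, time_hr = time_hr)
}

#' Simulate one plate of 8-peak rainbow calibration beads
#'
#' Bead peak intensities equal the manufacturer-assigned reference ERF values
#' multiplied by the plate's channel gain, with small lognormal acquisition
#' noise, so that fitting the calibration line recovers the gain.
#'
#' @param plate plate id.
#' @param gains named per-channel gains.
#' @param reference_erf 8 strictly increasing manufacturer-assigned values.
#' @param n_per_peak bead events acquired per peak.
#' @param noise_sd lognormal sd of bead intensities around each peak.
#' @return object of class `scnp_beads`: `plate`, `reference_erf`, and
#'   `channels` (per channel, a list of 8 intensity vectors).
#' @export
simulate_beads <- function(plate, gains,
                           reference_erf = c(806, 2159, 5824, 15638, 42000,
                                             112000, 301000, 810000),
                           n_per_peak = 300L, noise_sd = 0.04) {
  if (length(reference_erf) != 8L || any(diff(reference_erf) <= 0))
    stop("reference_erf must be 8 strictly increasing values")
  channels <- lapply(gains, function(g)
    lapply(reference_erf, function(r)
      stats::rlnorm(n_per_peak, log(r * g), noise_sd)))
  structure(list(plate = plate, reference_erf = reference_erf,
                 channels = channels), class = "scnp_beads")
}

# derive the list of wells a patient-tissue unit needs for a panel
panel_well_specs <- function(panel) {
  all_readouts <- intersect(unique(panel$readout), READOUT_CHANNELS)
  specs <- list(list(modulator = "autofluorescence", time_hr = 0.25,
                     channels = c(CORE_CHANNELS, all_readouts)))
  for (t in sort(unique(panel$time_hr))) {
    rd <- intersect(unique(panel$readout[panel$time_hr == t]), READOUT_CHANNELS)
    specs <- c(specs, list(list(modulator = "unmodulated", time_hr = t,
                                channels = c(CORE_CHANNELS, rd))))
  }
  mods <- unique(panel[!(panel$modulator %in% c("unmodulated", "autofluorescence")),
                       c("modulator", "time_hr")])
  for (i in seq_len(nrow(mods))) {
    sel <- panel$modulator == mods$modulator[i] & panel$time_hr == mods$time_hr[i]
    rd <- intersect(unique(panel$readout[sel]), READOUT_CHANNELS)
    specs <- c(specs, list(list(modulator = mods$modulator[i],
                                time_hr = mods$time_hr[i],
                                channels = c(CORE_CHANNELS, rd))))
  }
  specs
}

# solve the outcome-model intercept so the expected responder rate matches
solve_outcome_intercept <- function(config) {
  sgrid <- seq(0, 1, length.out = 401)
  cy_p <- c(better = 0.10, intermediate = 0.65, poor = 0.25)
  cy_e <- c(better = config$cyto_effect, intermediate = 0,
            poor = -config$cyto_effect)
  f <- function(b0) {
    m <- vapply(names(cy_p), function(cy)
      mean(stats::plogis(b0 + config$outcome_slope * sgrid + cy_e[[cy]])),
      numeric(1))
    sum(m * cy_p) - config$response_rate
  }
  stats::uniroot(f, c(-30, 30))$root
}

#' Simulate a full SCNP study cohort
#'
#' Generates patients (clinical covariates, cytogenetics with a missing
#' fraction, latent chemosensitivity and induction outcome), assigns
#' patient-tissue units to plates with multiplicative per-plate channel
#' gains, simulates every assay well the node panel requires (an
#' autofluorescence well, an unmodulated reference per exposure time, and one
#' well per modulated node) plus one rainbow-bead plate per assay plate.
#' Responders are drawn with higher latent chemosensitivity, so 24-hour
#' AraC+Dauno wells show cPARP up-shifts and CD34 down-shifts whose
#' magnitudes track the eventual outcome; for secondary-AML PB samples the
#' latent value is partially decoupled from the BM value according to
#' `config$pb_bm_discordance`.
#'
#' Reproducible: the same config (including its seed) yields identical output.
#'
#' @param config an [scnp_sim_config()].
#' @param panel node panel data.frame; see [default_node_panel()].
#' @return object of class `scnp_cohort`: `patients` (data.frame), `units`
#'   (patient-tissue-plate table), `wells` (named list of [scnp_events()]),
#'   `beads` (list of per-plate [simulate_beads()] objects), `config`,
#'   `panel`.
#' @export
simulate_cohort <- function(config = scnp_sim_config(),
                            panel = default_node_panel()) {
  stopifnot(inherits(config, "scnp_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  # --- patients -----------------------------------------------------------
  s <- stats::runif(n)
  onset <- ifelse(stats::runif(n) < config$secondary_frac, "secondary", "de_novo")
  d <- config$pb_bm_discordance
  latent_pb <- ifelse(onset == "secondary",
                      (1 - d) * s + d * stats::runif(n), s)
  cyto_true <- sample(c("better", "intermediate", "poor"), n, replace = TRUE,
                      prob = c(0.10, 0.65, 0.25))
  cyto_obs <- ifelse(stats::runif(n) < config$missing_cyto_frac,
                     "unknown", cyto_true)
  cy_e <- c(better = config$cyto_effect, intermediate = 0,
            poor = -config$cyto_effect)[cyto_true]
  b0 <- solve_outcome_intercept(config)
  trm <- stats::runif(n) < config$trm_rate
  p_resp <- stats::plogis(b0 + config$outcome_slope * s + cy_e)
  responder <- stats::runif(n) < p_resp
  outcome <- ifelse(trm, "TRM",
                    ifelse(responder,
                           ifelse(stats::runif(n) < config$cri_frac, "CRi", "CR"),
                           "RD"))
  flt3 <- stats::runif(n) < 0.20
  wbc <- round(stats::rlnorm(n, log(25), 0.9), 1)
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = round(stats::runif(n, 56, 84), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.45, 0.55)),
    onset = onset, outcome = outcome,
    wbc = wbc,
    bm_blast_pct = round(30 + 65 * stats::rbeta(n, 2, 1.2), 1),
    pb_blast_pct = round(15 + 75 * stats::rbeta(n, 2, 1.6), 1),
    hemoglobin = round(stats::rnorm(n, 9.5, 1.4), 1),
    platelets = round(stats::rlnorm(n, log(60), 0.6)),
    neutrophil_pct = round(stats::runif(n, 0, 40), 1),
    monocyte_pct = round(stats::runif(n, 0, 15), 1),
    performance_status = sample(c("0-1", "2-3"), n, replace = TRUE,
                                prob = c(0.75, 0.25)),
    fab_group = sample(c("M0/M1/M2/M7", "other"), n, replace = TRUE,
                       prob = c(0.40, 0.60)),
    cytogenetic_risk = cyto_obs, cyto_true = cyto_true,
    flt3_itd = ifelse(flt3, "mutant", "wildtype"),
    flt3_itd_ratio = ifelse(flt3, round(stats::runif(n, 0.05, 1.5), 3), 0),
    npm1 = ifelse(stats::runif(n) < 0.25, "mutant", "wildtype"),
    latent_chemosensitivity = s, latent_pb = latent_pb,
    responsiveness = exp(stats::rnorm(n, 0, 0.3)),
    stringsAsFactors = FALSE)
  patients$neutrophil_abs <- round(patients$wbc * patients$neutrophil_pct / 100, 2)
  patients$monocyte_abs <- round(patients$wbc * patients$monocyte_pct / 100, 2)

  has_bm <- stats::runif(n) < config$tissue_prob[["BM"]]
  has_pb <- stats::runif(n) < config$tissue_prob[["PB"]]
  has_bm[!has_bm & !has_pb] <- TRUE
  patients$tissue_bm <- has_bm
  patients$tissue_pb <- has_pb

  # --- plates and wells ---------------------------------------------------
  units <- data.frame(
    patient_id = c(patients$patient_id[has_bm], patients$patient_id[has_pb]),
    tissue = c(rep("BM", sum(has_bm)), rep("PB", sum(has_pb))),
    stringsAsFactors = FALSE)
  units <- units[order(units$patient_id, units$tissue), , drop = FALSE]
  units$plate <- ((seq_len(nrow(units)) - 1L) %/% config$plate_size) + 1L
  n_plates <- max(units$plate)
  plate_gains <- lapply(seq_len(n_plates), function(p)
    stats::setNames(stats::rlnorm(length(FLUOR_CHANNELS), 0, config$plate_gain_sd),
                    FLUOR_CHANNELS))
  beads <- lapply(seq_len(n_plates), function(p)
    simulate_beads(plate = p, gains = plate_gains[[p]]))

  specs <- panel_well_specs(panel)
  wells <- vector("list", nrow(units) * length(specs))
  widx <- 0L
  for (i in seq_len(nrow(units))) {
    pid <- units$patient_id[i]; tis <- units$tissue[i]; plate <- units$plate[i]
    prow <- patients[patients$patient_id == pid, ]
    prow$latent <- if (tis == "PB") prow$latent_pb else prow$latent_chemosensitivity
    # each apoptosis node measures the latent with its own biological noise
    clamp01 <- function(x) min(max(x, 0), 1)
    prow$latent_cparp <- clamp01(prow$latent +
      stats::rnorm(1, 0, config$node_noise_cparp))
    prow$latent_cd34 <- clamp01(prow$latent +
      stats::rnorm(1, 0, config$node_noise_cd34))
    prow$latent_cparp_weak <- clamp01(prow$latent +
      stats::rnorm(1, 0, config$node_noise_weak))
    prow$latent_cd34_weak <- clamp01(prow$latent +
      stats::rnorm(1, 0, config$node_noise_weak))
    offsets <- stats::setNames(stats::rnorm(length(FLUOR_CHANNELS), 0,
                                            config$noise_patient),
                               FLUOR_CHANNELS)
    for (sp in specs) {
      w <- simulate_well(prow, tis, sp$modulator, sp$time_hr, sp$channels,
                         config = config, gains = plate_gains[[plate]],
                         offsets = offsets)
      w$plate <- plate
      widx <- widx + 1L
      wells[[widx]] <- w
    }
  }
  names(wells) <- vapply(wells, `[[`, character(1), "well_id")
  structure(list(patients = patients, units = units, wells = wells,
                 beads = beads, config = config, panel = panel),
            class = "scnp_cohort")
}

#' @export
print.scnp_cohort <- function(x, ...) {
  cat(sprintf("<scnp_cohort> %d patients, %d patient-tissue units, %d wells, %d plates (seed %d)\n",
              nrow(x$patients), nrow(x$units), length(x$wells),
              length(x$beads), x$config$seed))
  print(table(x$patients$outcome))
  invisible(x)
}
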