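test_that("configuration validation rejects invalid inputs", {
  expect_error(scnp_sim_config(n_patients = 0), "positive")
  expect_error(scnp_sim_config(response_rate = 1.4), "probability")
  expect_error(scnp_sim_config(trm_rate = -0.1), "probability")
  expect_error(scnp_sim_config(effect_cparp = Inf), "finite")
  expect_error(scnp_sim_config(tissue_prob = c(BM = 0.5)), "named")
})

test_that("simulation is reproducible given the seed", {
  cfg <- small_config(n = 8, events = 300, seed = 123)
  a <- simulate_cohort(cfg, panel = apoptosis_panel())
  b <- simulate_cohort(cfg, panel = apoptosis_panel())
  expect_identical(a$patients, b$patients)
  expect_identical(names(a$wells), names(b$wells))
  expect_identical(a$wells[[1]]$data, b$wells[[1]]$data)
  expect_identical(a$beads[[1]]$channels$CD45[[3]],
                   b$beads[[1]]$channels$CD45[[3]])
  d <- simulate_cohort(small_config(n = 8, events = 300, seed = 124),
                       panel = apoptosis_panel())
  expect_false(identical(a$wells[[1]]$data, d$wells[[1]]$data))
})

test_that("simulate_well is deterministic under a fixed RNG state", {
  pat <- list(patient_id = "P1", bm_blast_pct = 60, pb_blast_pct = 40)
  cfg <- scnp_sim_config()
  set.seed(5)
  w1 <- simulate_well(pat, "BM", "unmodulated", 0.25,
                      c("FSC", "SSC", "AquaAmine", "CD45"), cfg)
  set.seed(5)
  w2 <- simulate_well(pat, "BM", "unmodulated", 0.25,
                      c("FSC", "SSC", "AquaAmine", "CD45"), cfg)
  expect_identical(w1$data, w2$data)
  expect_error(simulate_well(pat, "BM", "unmodulated", 0.25, c("FSC", "pFOO"),
                             cfg), "unknown channel")
})

test_that("event counts follow the configured Poisson mean", {
  set.seed(6)
  cfg <- scnp_sim_config(mean_events = 400)
  pat <- list(patient_id = "P1", bm_blast_pct = 60, pb_blast_pct = 40)
  n <- replicate(100, simulate_well(pat, "BM", "unmodulated", 0.25,
                                    c("FSC", "SSC"), cfg)$n_events)
  expect_lt(abs(mean(n) - 400), 4 * sqrt(400 / 100))
  expect_lt(abs(var(n) / 400 - 1), 0.5)
})

test_that("every patient has at least one tissue and valid fields", {
  coh <- simulate_cohort(small_config(n = 60, events = 100, seed = 9,
                                      tissue_prob = c(BM = 0.3, PB = 0.3)),
                         panel = apoptosis_panel())
  p <- coh$patients
  expect_true(all(p$tissue_bm | p$tissue_pb))
  expect_true(all(p$bm_blast_pct >= 0 & p$bm_blast_pct <= 100))
  expect_true(all(p$outcome %in% c("CR", "CRi", "RD", "TRM")))
  expect_true(all(p$latent_chemosensitivity >= 0 &
                  p$latent_chemosensitivity <= 1))
  expect_true(all(p$cytogenetic_risk %in%
                  c("better", "intermediate", "poor", "unknown")))
})

test_that("responders carry higher latent chemosensitivity and ~72% prevalence", {
  coh <- simulate_cohort(scnp_sim_config(n_patients = 600, mean_events = 1,
                                         seed = 10),
                         panel = apoptosis_panel()[1, ])
  p <- coh$patients
  nontrm <- p[p$outcome != "TRM", ]
  rate <- mean(nontrm$outcome %in% c("CR", "CRi"))
  expect_lt(abs(rate - 0.72), 0.06)
  expect_gt(mean(nontrm$latent_chemosensitivity[nontrm$outcome %in% c("CR", "CRi")]),
            mean(nontrm$latent_chemosensitivity[nontrm$outcome == "RD"]))
  expect_lt(abs(mean(p$outcome == "TRM") - 0.15), 0.05)
})

test_that("zero planted effect leaves no responder/RD difference in the cPARP node", {
  cfg <- small_config(n = 60, events = 700, seed = 11,
                      effect_cparp = 0, effect_cd34 = 0, effect_death = 0)
  coh <- simulate_cohort(cfg, panel = apoptosis_panel())
  f <- cohort_features(coh)
  uu <- f$X[[cparp_feature]]
  expect_lt(abs(mean(uu[f$y == 1], na.rm = TRUE) -
                mean(uu[f$y == 0], na.rm = TRUE)), 0.05)
  expect_lt(abs(mean(uu, na.rm = TRUE) - 0.5), 0.05)
})

test_that("the planted responder/RD Uu gap grows with the cPARP effect size", {
  gap <- function(eff) {
    gaps <- sapply(1:3, function(s) {
      cfg <- small_config(n = 50, events = 500, seed = 100 + s,
                          effect_cparp = eff)
      f <- cohort_features(simulate_cohort(cfg, panel = apoptosis_panel()))
      uu <- f$X[[cparp_feature]]
      mean(uu[f$y == 1], na.rm = TRUE) - mean(uu[f$y == 0], na.rm = TRUE)
    })
    mean(gaps)
  }
  g <- c(gap(0), gap(0.8), gap(2))
  expect_true(all(diff(g) > 0))
})

test_that("simulator population labels respect the gating hierarchy by construction", {
  set.seed(12)
  cfg <- scnp_sim_config()
  pat <- list(patient_id = "P1", bm_blast_pct = 70, pb_blast_pct = 50)
  w <- simulate_well(pat, "BM", "unmodulated", 0.25,
                     c("FSC", "SSC", "AquaAmine", "CD45"), cfg,
                     n_events = 4000)
  auto <- simulate_well(pat, "BM", "autofluorescence", 0.25,
                        c("FSC", "SSC", "AquaAmine", "CD45"), cfg,
                        n_events = 4000)
  g <- gate_hierarchy(w, aqua_threshold = viability_threshold(auto$data$AquaAmine))
  lab <- attr(w$data, "population")
  # labeled dead cells are overwhelmingly excluded from the viable gate
  expect_lt(sum(g$viable & lab == "dead") / max(sum(lab == "dead"), 1), 0.1)
  # gated blasts are overwhelmingly labeled blasts
  expect_gt(sum(g$blast & lab == "blast") / sum(g$blast), 0.85)
})
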