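sim_one_well <- function(patient = list(patient_id = "P1", bm_blast_pct = 70,
                                        pb_blast_pct = 50),
                         modulator = "unmodulated", n_events = 3000, ...) {
  simulate_well(patient, "BM", modulator, 0.25,
                channels = c("FSC", "SSC", "AquaAmine", "CD45", "CD34", "cPARP"),
                config = scnp_sim_config(...), n_events = n_events)
}

test_that("gate masks are always nested over random wells", {
  set.seed(91)
  for (i in 1:40) {
    w <- sim_one_well(list(patient_id = "P1",
                           bm_blast_pct = runif(1, 5, 95), pb_blast_pct = 50),
                      n_events = sample(500:3000, 1), seed = i)
    g <- gate_hierarchy(w, aqua_threshold = exp(runif(1, 4, 6)),
                        cparp_split = exp(runif(1, 4.5, 5.5)))
    expect_true(all(g$viable[g$blast]))
    expect_true(all(g$intact[g$viable]))
    expect_true(all(g$blast[g$healthy_blast]))
    expect_identical(unname(g$counts),
                     c(sum(g$intact), sum(g$viable), sum(g$blast),
                       sum(g$healthy_blast)))
  }
})

test_that("an unattainable viability threshold empties the downstream gates", {
  set.seed(92)
  w <- sim_one_well()
  g <- gate_hierarchy(w, aqua_threshold = 0)
  expect_gt(g$counts[["intact"]], 0)
  expect_identical(g$counts[["viable"]], 0L)
  expect_identical(g$counts[["blast"]], 0L)
})

test_that("a pure-blast well is recovered at the rate the gate definitions imply", {
  # the default gates trim ~4% per scatter channel (2nd-98th percentile
  # rectangle), ~2% at the viability threshold and ~2% at the SSC cap, so a
  # well containing only labeled blasts keeps >= ~85% of events
  set.seed(93)
  cfg <- scnp_sim_config(debris_frac = 0, dead_frac = 0, seed = 93)
  pat <- list(patient_id = "P1", bm_blast_pct = 100, pb_blast_pct = 100)
  w <- simulate_well(pat, "BM", "unmodulated", 0.25,
                     c("FSC", "SSC", "AquaAmine", "CD45"), cfg,
                     n_events = 5000)
  expect_true(all(attr(w$data, "population") == "blast"))
  auto <- simulate_well(pat, "BM", "autofluorescence", 0.25,
                        c("FSC", "SSC", "AquaAmine", "CD45"), cfg,
                        n_events = 5000)
  thr <- viability_threshold(auto$data$AquaAmine)
  g <- gate_hierarchy(w, aqua_threshold = thr)
  expect_gte(g$counts[["blast"]] / w$n_events, 0.85)
})

test_that("an empty well warns and returns zero counts", {
  e <- scnp_events(data.frame(FSC = numeric(0), SSC = numeric(0),
                              AquaAmine = numeric(0), CD45 = numeric(0)),
                   "w", "p", "BM", "unmodulated", 0.25)
  expect_warning(g <- gate_hierarchy(e, aqua_threshold = 100), "empty")
  expect_identical(sum(g$counts), 0L)
})

test_that("missing gating channels are an error", {
  e <- scnp_events(data.frame(FSC = 1:3, SSC = 1:3), "w", "p", "BM",
                   "unmodulated", 0.25)
  expect_error(gate_hierarchy(e, aqua_threshold = 1), "missing gating channel")
})

test_that("the cPARP split point is the interpolated 98th percentile", {
  g <- cparp_negative_gate(c(rep(10, 50), rep(1000, 50)), 1:100)
  expect_equal(g$split_point, 98.02)
  expect_identical(sum(g$mask), 50L)
  # constant reference: everything below is negative
  g2 <- cparp_negative_gate(c(1, 2, 3), rep(5, 20))
  expect_true(all(g2$mask))
  expect_error(cparp_negative_gate(1:3, numeric(0)), "empty")
})

test_that("the CD45 cluster split separates dim blasts from bright lymphocytes", {
  set.seed(94)
  w <- sim_one_well(list(patient_id = "P1", bm_blast_pct = 50,
                         pb_blast_pct = 50), n_events = 6000,
                    debris_frac = 0, dead_frac = 0)
  thr <- exp(5.5)
  g <- gate_hierarchy(w, aqua_threshold = thr)
  lab <- attr(w$data, "population")
  recall <- sum(g$blast & lab == "blast") / sum(lab == "blast")
  purity <- sum(g$blast & lab == "blast") / sum(g$blast)
  expect_gt(recall, 0.85)
  expect_gt(purity, 0.9)
})
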