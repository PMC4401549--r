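fake_stream <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", 1:n),
    response = sample(c("CR/CRi", "RD"), n, TRUE, prob = c(0.6, 0.4)),
    tissues = sample(c("BM", "PB", "BM+PB"), n, TRUE),
    cyto = sample(c("better", "intermediate", "poor", "missing"), n, TRUE,
                  prob = c(0.1, 0.5, 0.2, 0.2)),
    trial_arm = sample(paste0("trial", 1:4), n, TRUE),
    flt3 = sample(c("mutant", "wildtype", "missing"), n, TRUE,
                  prob = c(0.2, 0.7, 0.1)),
    readout_avail = sample(c("full", "partial"), n, TRUE),
    stringsAsFactors = FALSE)
}
six_factors <- c("response", "tissues", "cyto", "trial_arm", "flt3",
                 "readout_avail")

max_factor_diff <- function(pats, arm, factors) {
  max(sapply(factors, function(f) {
    tab <- table(pats[[f]], arm)
    if (ncol(tab) == 1) max(tab) else max(abs(tab[, 1] - tab[, 2]))
  }))
}

test_that("the first patient in an empty state is a fair coin flip", {
  p1 <- fake_stream(1)
  arms <- sapply(1:40, function(s)
    as.character(minimization_assign(p1, six_factors, seed = s)$assignment))
  expect_setequal(unique(arms), c("Training", "Validation"))
})

test_that("with p = 1 the strictly worse arm is never chosen", {
  # exhaustive 2-factor enumeration: preload arm Training ahead on every level
  for (l1 in c("a", "b")) for (l2 in c("x", "y")) {
    state <- allocation_state(list(f1 = c("a", "b"), f2 = c("x", "y")))
    state$counts$f1["Training", ] <- 5L
    state$counts$f2["Training", ] <- 5L
    r <- minimization_assign(data.frame(f1 = l1, f2 = l2),
                             c("f1", "f2"), state = state,
                             p_deterministic = 1, seed = 1)
    expect_identical(as.character(r$assignment), "Validation")
  }
})

test_that("unknown factors or levels are errors", {
  expect_error(minimization_assign(fake_stream(3), c("response", "zzz")),
               "unknown factor")
  state <- allocation_state(list(f1 = c("a", "b")))
  expect_error(minimization_assign(data.frame(f1 = "c"), "f1", state = state),
               "unknown level")
})

test_that("minimization balances factors better than simple randomization", {
  set.seed(55)
  diffs <- t(sapply(1:40, function(s) {
    pats <- fake_stream(200, seed = 1000 + s)
    mini <- minimization_assign(pats, six_factors, seed = s)$assignment
    simple <- factor(sample(c("Training", "Validation"), 200, TRUE),
                     levels = c("Training", "Validation"))
    c(mini = max_factor_diff(pats, mini, six_factors),
      simple = max_factor_diff(pats, simple, six_factors))
  }))
  expect_lt(mean(diffs[, "mini"]), mean(diffs[, "simple"]))
  expect_lt(quantile(diffs[, "mini"], 0.95), quantile(diffs[, "simple"], 0.95))
})

test_that("single-factor minimization at p = 1 keeps every level within 1", {
  set.seed(56)
  for (s in 1:10) {
    pats <- data.frame(f = sample(c("a", "b", "c"), 120, TRUE))
    r <- minimization_assign(pats, "f", p_deterministic = 1, seed = s)
    tab <- table(pats$f, r$assignment)
    expect_lte(max(abs(tab[, 1] - tab[, 2])), 1)
  }
})

test_that("missing values are balanced as their own level", {
  pats <- fake_stream(60, seed = 3)
  pats$cyto[1:10] <- NA
  r <- minimization_assign(pats, six_factors, seed = 4)
  expect_identical(length(r$assignment), 60L)
  expect_true("missing" %in% colnames(r$state$counts$cyto))
})

test_that("analysis sets exclude TRM and unassessable patients with reasons", {
  pats <- data.frame(
    patient_id = sprintf("P%02d", 1:20),
    outcome = c(rep("CR", 8), rep("RD", 5), rep("TRM", 5), rep("CRi", 2)),
    assignment = rep(c("Training", "Validation"), 10),
    stringsAsFactors = FALSE)
  ev <- data.frame(patient_id = rep(pats$patient_id, each = 2),
                   tissue = rep(c("BM", "PB"), 20),
                   evaluable = rep(TRUE, 40), stringsAsFactors = FALSE)
  ev$evaluable[ev$patient_id == "P01"] <- FALSE   # no assessable sample
  ev$evaluable[ev$patient_id == "P02" & ev$tissue == "PB"] <- FALSE
  sets <- build_analysis_sets(pats, ev)
  in_any <- unique(unlist(sets$sets))
  expect_false(any(pats$patient_id[pats$outcome == "TRM"] %in% in_any))
  expect_identical(sum(sets$exclusions$reason == "TRM outcome"), 5L)
  expect_true("P01" %in% sets$exclusions$patient_id)
  # conservation: every patient is either in some set or excluded
  expect_setequal(c(in_any, sets$exclusions$patient_id), pats$patient_id)
  # a patient with both tissues appears once in the BM and once in the PB set
  expect_true("P03" %in% sets$sets[["Training.BM"]] ||
              "P03" %in% sets$sets[["Validation.BM"]])
  for (s in sets$sets) expect_identical(anyDuplicated(s), 0L)
  # P02 keeps BM but not PB
  expect_false("P02" %in% c(sets$sets[["Training.PB"]],
                            sets$sets[["Validation.PB"]]))
})

test_that("analysis-set construction is idempotent and order invariant", {
  pats <- fake_stream(30, seed = 9)
  pats$outcome <- sample(c("CR", "CRi", "RD", "TRM"), 30, TRUE)
  pats$assignment <- sample(c("Training", "Validation"), 30, TRUE)
  ev <- data.frame(patient_id = pats$patient_id, tissue = "BM",
                   evaluable = TRUE, stringsAsFactors = FALSE)
  a <- build_analysis_sets(pats, ev)
  b <- build_analysis_sets(pats[sample(30), ], ev)
  expect_identical(lapply(a$sets, sort), lapply(b$sets, sort))
})

test_that("imputation follows the clinical rules with provenance", {
  rec <- data.frame(patient_id = c("A", "B", "C", "D"),
                    cytogenetic_risk = c("unknown", "poor", NA, "better"),
                    wbc = c(10, NA, 30, 50),
                    onset = c("de_novo", NA, "de_novo", "secondary"),
                    stringsAsFactors = FALSE)
  out <- impute_clinical(rec)
  expect_identical(out$cytogenetic_risk, c("intermediate", "poor",
                                           "intermediate", "better"))
  expect_equal(out$wbc[2], median(c(10, 30, 50)))
  expect_identical(out$onset[2], "de_novo")
  prov <- attr(out, "imputation")
  expect_identical(sort(unique(prov$rule)),
                   c("reference_median", "reference_mode",
                     "unknown_to_intermediate"))
  # no missing values: output identical, empty provenance
  clean <- impute_clinical(out)
  attr(clean, "imputation") <- NULL
  cmp <- out; attr(cmp, "imputation") <- NULL
  expect_identical(clean, cmp)
  # reference statistics come from the reference records, not the target
  ref <- data.frame(patient_id = "Z", cytogenetic_risk = "poor", wbc = 100,
                    onset = "de_novo", stringsAsFactors = FALSE)
  out2 <- impute_clinical(rec, reference = ref)
  expect_equal(out2$wbc[2], 100)
  # an all-missing numeric column cannot be imputed
  rec$wbc <- NA_real_
  expect_error(impute_clinical(rec), "all values missing")
})
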