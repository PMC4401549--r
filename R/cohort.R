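# Cohort bookkeeping: Pocock-Simon minimization randomization,
# analysis-set construction, clinical-covariate imputation.

#' Initialize a minimization allocation state
#'
#' @param factors named list mapping each balancing-factor name to its level
#'   set (include `"missing"` if missing values may occur).
#' @param arms arm labels.
#' @return object of class `scnp_allocation`: per-factor arm-by-level count
#'   matrices.
#' @export
allocation_state <- function(factors, arms = c("Training", "Validation")) {
  if (length(arms) < 2L) stop("need at least two arms")
  counts <- lapply(factors, function(lv)
    matrix(0L, nrow = length(arms), ncol = length(lv),
           dimnames = list(arms, lv)))
  structure(list(counts = counts, arms = arms,
                 factors = names(factors)), class = "scnp_allocation")
}

#' Pocock-Simon minimization assignment
#'
#' Assigns each arriving patient to the arm that minimizes the total
#' marginal imbalance over the balancing factors (range method, unit factor
#' weights): for each candidate arm, the patient is provisionally added and
#' the per-factor imbalance (max minus min arm count at the patient's level)
#' is summed; the arm with the smallest total is chosen with probability
#' `p_deterministic`, the other arm otherwise. Exact ties are resolved by a
#' fair coin. Missing factor values are treated as the level `"missing"`.
#'
#' @param patients data.frame of arriving patients (processed in row order).
#' @param factors character vector of balancing-factor column names.
#' @param state optional [allocation_state()] to continue from; by default a
#'   fresh state is built with levels taken from the data.
#' @param p_deterministic probability of assigning the imbalance-minimizing
#'   arm (1 = always).
#' @param arms arm labels (used when `state` is NULL).
#' @param seed RNG seed.
#' @return list with `assignment` (factor of arm labels, one per patient)
#'   and the final `state`.
#' @export
minimization_assign <- function(patients, factors, state = NULL,
                                p_deterministic = 0.8,
                                arms = c("Training", "Validation"),
                                seed = NULL) {
  check_prob(p_deterministic, "p_deterministic")
  miss <- setdiff(factors, names(patients))
  if (length(miss)) stop("unknown factor(s): ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  vals <- lapply(stats::setNames(factors, factors), function(f) {
    v <- as.character(patients[[f]])
    v[is.na(v)] <- "missing"
    v
  })
  if (is.null(state)) {
    state <- allocation_state(lapply(vals, function(v) sort(unique(v))),
                              arms = arms)
  }
  arms <- state$arms
  n <- nrow(patients)
  assignment <- character(n)
  for (i in seq_len(n)) {
    totals <- vapply(seq_along(arms), function(a) {
      s <- 0
      for (f in factors) {
        lv <- vals[[f]][i]
        if (!lv %in% colnames(state$counts[[f]]))
          stop("unknown level '", lv, "' for factor '", f, "'")
        cnt <- state$counts[[f]][, lv]
        cnt[a] <- cnt[a] + 1L
        s <- s + (max(cnt) - min(cnt))
      }
      s
    }, numeric(1))
    best <- which(totals == min(totals))
    pick <- if (length(best) == length(arms)) {
      sample(seq_along(arms), 1L)
    } else {
      b <- if (length(best) > 1L) sample(best, 1L) else best
      if (stats::runif(1) <= p_deterministic) b
      else sample(setdiff(seq_along(arms), b), 1L)
    }
    assignment[i] <- arms[pick]
    for (f in factors)
      state$counts[[f]][pick, vals[[f]][i]] <-
        state$counts[[f]][pick, vals[[f]][i]] + 1L
  }
  list(assignment = factor(assignment, levels = arms), state = state)
}

#' Build tissue-specific analysis sets
#'
#' Filters randomized patients into per-arm, per-tissue analysis sets:
#' patients with a TRM outcome are excluded (the assay measures blast
#' chemosensitivity, not comorbidity), as are patients with no
#' SCNP-assessable sample. Within each analysis set every patient
#' contributes exactly one sample (one tissue); a patient with both tissues
#' assessable appears in the BM set and in the PB set of their arm.
#'
#' @param patients data.frame with `patient_id`, `outcome`
#'   (CR/CRi/RD/TRM) and `assignment` (arm label) columns.
#' @param scnp_evaluability data.frame with `patient_id`, `tissue`,
#'   `evaluable` rows describing which samples met the assay evaluability
#'   criteria.
#' @return object of class `scnp_analysis_sets`: `sets` (named list
#'   `<arm>.<tissue>` of patient-id vectors) and `exclusions` (data.frame
#'   `patient_id`, `reason`).
#' @export
build_analysis_sets <- function(patients, scnp_evaluability) {
  need <- c("patient_id", "outcome", "assignment")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("patients lacks column(s): ", paste(miss, collapse = ", "))
  excl <- list()
  ok_outcome <- patients$outcome %in% c("CR", "CRi", "RD")
  for (i in which(patients$outcome == "TRM"))
    excl[[length(excl) + 1L]] <- data.frame(
      patient_id = patients$patient_id[i], reason = "TRM outcome",
      stringsAsFactors = FALSE)
  for (i in which(!ok_outcome & patients$outcome != "TRM"))
    excl[[length(excl) + 1L]] <- data.frame(
      patient_id = patients$patient_id[i],
      reason = paste0("outcome not CR/CRi/RD: ", patients$outcome[i]),
      stringsAsFactors = FALSE)
  ev <- scnp_evaluability[scnp_evaluability$evaluable, , drop = FALSE]
  has_sample <- patients$patient_id %in% ev$patient_id
  for (i in which(ok_outcome & !has_sample))
    excl[[length(excl) + 1L]] <- data.frame(
      patient_id = patients$patient_id[i],
      reason = "no SCNP-assessable sample", stringsAsFactors = FALSE)
  keep <- patients[ok_outcome & has_sample, , drop = FALSE]
  sets <- list()
  for (arm in unique(as.character(keep$assignment))) {
    for (tis in sort(unique(ev$tissue))) {
      ids <- keep$patient_id[keep$assignment == arm &
                               keep$patient_id %in%
                               ev$patient_id[ev$tissue == tis]]
      if (anyDuplicated(ids)) stop("duplicate patient in analysis set")
      sets[[paste(arm, tis, sep = ".")]] <- ids
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(0), reason = character(0))
  structure(list(sets = sets, exclusions = exclusions),
            class = "scnp_analysis_sets")
}

#' Impute missing clinical covariates
#'
#' Applies the study's imputation rules: unknown cytogenetic risk is imputed
#' as intermediate (as is done in clinical practice); other missing numeric
#' covariates are imputed with the median of the observed values in the
#' reference records (by default the training records, so validation-set
#' imputation does not leak); missing categorical covariates with the
#' reference mode. An all-missing column is an error. Imputation provenance
#' is recorded per (patient, field) in the `"imputation"` attribute.
#'
#' @param records patient-record data.frame.
#' @param reference records supplying the imputation statistics (defaults to
#'   `records` itself).
#' @return records with missing values filled; provenance in
#'   `attr(, "imputation")`.
#' @export
impute_clinical <- function(records, reference = NULL) {
  reference <- reference %||% records
  prov <- list()
  note <- function(pid, field, rule)
    prov[[length(prov) + 1L]] <<- data.frame(patient_id = pid, field = field,
                                             rule = rule,
                                             stringsAsFactors = FALSE)
  if ("cytogenetic_risk" %in% names(records)) {
    unk <- is.na(records$cytogenetic_risk) |
      records$cytogenetic_risk == "unknown"
    if (any(unk)) {
      note(records$patient_id[unk], "cytogenetic_risk",
           "unknown_to_intermediate")
      records$cytogenetic_risk[unk] <- "intermediate"
    }
  }
  skip <- c("patient_id", "outcome", "cytogenetic_risk",
            "latent_chemosensitivity", "latent_pb", "cyto_true")
  for (field in setdiff(names(records), skip)) {
    nas <- is.na(records[[field]])
    if (!any(nas)) next
    ref <- reference[[field]]
    if (all(is.na(ref))) stop("cannot impute '", field, "': all values missing")
    if (is.numeric(records[[field]])) {
      records[[field]][nas] <- stats::median(ref, na.rm = TRUE)
      note(records$patient_id[nas], field, "reference_median")
    } else {
      tab <- table(ref[!is.na(ref)])
      records[[field]][nas] <- names(tab)[which.max(tab)]
      note(records$patient_id[nas], field, "reference_mode")
    }
  }
  attr(records, "imputation") <- if (length(prov)) do.call(rbind, prov) else
    data.frame(patient_id = character(0), field = character(0),
               rule = character(0))
  records
}
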