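#' Input variable lists for the clinical classifiers
#'
#' Level 1 uses only clinical factors available at diagnosis: age, BM blast
#' percentage, white blood cell count, peripheral blast percentage,
#' neutrophil and monocyte counts (percent and absolute), hemoglobin,
#' platelet count, performance status (0-1 vs 2-3), FAB class group
#' (M0/M1/M2/M7 vs other) and AML onset (de novo vs secondary). Level 2 adds
#' cytogenetic risk group, the percentage of CD34+ cells from the SCNP
#' phenotyping well, FLT3-ITD (continuous allelic ratio and binary) and NPM1
#' mutation status.
#'
#' @param level 1 or 2.
#' @return character vector of required patient-record fields.
#' @export
clinical_inputs <- function(level = 1L) {
  lvl1 <- c("age", "bm_blast_pct", "wbc", "pb_blast_pct",
            "neutrophil_pct", "neutrophil_abs", "monocyte_pct",
            "monocyte_abs", "hemoglobin", "platelets",
            "performance_status", "fab_group", "onset")
  if (level == 1L) return(lvl1)
  c(lvl1, "cytogenetic_risk", "cd34_pct", "flt3_itd_ratio", "flt3_itd", "npm1")
}

clinical_design <- function(records, level) {
  X <- data.frame(
    age = records$age, bm_blast_pct = records$bm_blast_pct,
    wbc = records$wbc, pb_blast_pct = records$pb_blast_pct,
    neutrophil_pct = records$neutrophil_pct,
    neutrophil_abs = records$neutrophil_abs,
    monocyte_pct = records$monocyte_pct, monocyte_abs = records$monocyte_abs,
    hemoglobin = records$hemoglobin, platelets = records$platelets,
    performance_2_3 = as.numeric(records$performance_status == "2-3"),
    fab_m0127 = as.numeric(records$fab_group == "M0/M1/M2/M7"),
    onset_secondary = as.numeric(records$onset == "secondary"))
  if (level == 2L) {
    if (any(records$cytogenetic_risk == "unknown"))
      stop("unknown cytogenetic risk present; run impute_clinical() first")
    X$cyto_better <- as.numeric(records$cytogenetic_risk == "better")
    X$cyto_poor <- as.numeric(records$cytogenetic_risk == "poor")
    X$cd34_pct <- records$cd34_pct
    X$flt3_itd_ratio <- records$flt3_itd_ratio
    X$flt3_itd_mutant <- as.numeric(records$flt3_itd == "mutant")
    X$npm1_mutant <- as.numeric(records$npm1 == "mutant")
  }
  X
}

#' Build a clinical response classifier (level 1 or 2)
#'
#' Fits an L1-penalized logistic regression of induction response (CR/CRi vs
#' RD) on the level's clinical input list. If the penalty shrinks every
#' coefficient to zero, no classifier can be constructed from those inputs
#' and the model is flagged accordingly. For constructible models the
#' out-of-bag AUROC of a logistic refit on the selected variables is
#' reported.
#'
#' Imputation must be applied beforehand ([impute_clinical()]); any missing
#' required field is a precondition error. The level-2 CD34+ percentage
#' comes from the SCNP phenotyping well and is supplied via `cd34_pct`
#' (named by patient id) when not already a record column.
#'
#' @param records patient-record data.frame restricted to CR/CRi/RD
#'   outcomes, with an `outcome` column.
#' @param level 1 (clinical only) or 2 (plus cytogenetic/molecular inputs).
#' @param cd34_pct optional named numeric vector of CD34+ percentages,
#'   merged into the records by `patient_id`.
#' @param rule penalty-selection rule, see [fit_penalized_logistic()].
#' @param B_oob bootstrap resamples for the OOB AUROC.
#' @param seed RNG seed.
#' @return list of class `scnp_clinical_model`: `level`, `inputs`,
#'   `coefficients`, `constructible`, `selected`, `oob_auroc`.
#' @export
build_dx_clinical <- function(records, level = 1L, cd34_pct = NULL,
                              rule = "1se", B_oob = 200L, seed = NULL) {
  if (!level %in% c(1L, 2L)) stop("level must be 1 or 2")
  if (any(records$outcome == "TRM"))
    stop("TRM patients must be excluded before model building")
  if (level == 2L && !is.null(cd34_pct)) {
    if (is.null(names(cd34_pct))) stop("cd34_pct must be named by patient id")
    records$cd34_pct <- unname(cd34_pct[records$patient_id])
  }
  need <- clinical_inputs(level)
  missing_fields <- setdiff(need, names(records))
  if (length(missing_fields))
    stop("missing required field(s): ", paste(missing_fields, collapse = ", "),
         "; run impute_clinical() / supply cd34_pct")
  if (anyNA(records[need]))
    stop("missing values in required inputs; run impute_clinical() first")
  y <- as.integer(records$outcome %in% c("CR", "CRi"))
  X <- clinical_design(records, level)
  pen <- fit_penalized_logistic(X, y, rule = rule, seed = seed)
  constructible <- length(pen$nonzero) > 0L
  oob <- NA_real_
  if (constructible) {
    oob <- oob_auroc(X[pen$nonzero], y, B = B_oob, seed = seed)$auroc
  }
  structure(list(level = level, inputs = need,
                 coefficients = pen$coefficients,
                 constructible = constructible, selected = pen$nonzero,
                 oob_auroc = oob, lambda = pen$lambda),
            class = "scnp_clinical_model")
}

#' @export
print.scnp_clinical_model <- function(x, ...) {
  cat(sprintf("<scnp_clinical_model> level %d: %s\n", x$level,
              if (x$constructible) "constructible" else
                "not constructible (all coefficients shrunk to zero)"))
  if (x$constructible)
    cat("  selected:", paste(x$selected, collapse = ", "),
        sprintf("| OOB AUROC %.3f\n", x$oob_auroc))
  invisible(x)
}

#' Percentage of CD34+ cells from the phenotyping well
#'
#' Extracts the CD34 phenotyping feature (percent of blast cells above the
#' autofluorescence CD34 split) from a node table, for use as the level-2
#' clinical input.
#'
#' @param node_table output of [compute_node_table()].
#' @param tissue tissue whose phenotyping values to use.
#' @return named numeric vector (patient id -> CD34+ percent).
#' @export
cd34_pct_from_nodes <- function(node_table, tissue = "BM") {
  sel <- node_table$metric == "PctPos" & node_table$readout == "CD34" &
    node_table$tissue == tissue
  if (!any(sel)) stop("node table has no CD34 phenotyping records")
  stats::setNames(ifelse(node_table$evaluable[sel], node_table$value[sel],
                         NA_real_),
                  node_table$patient_id[sel])
}
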