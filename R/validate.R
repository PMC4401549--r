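#' Test whether the SCNP score predicts response independently of a clinical score
#'
#' Fits an unpenalized logistic regression of induction response on the SCNP
#' classifier score and a clinical classifier score jointly (each controlling
#' for the other) and reports the p-value for the SCNP coefficient. A
#' non-significant p-value is expected if the SCNP score is redundant given
#' the clinical score.
#'
#' @param scnp_scores,clinical_scores numeric score vectors, one per patient.
#' @param outcomes binary response labels (see [auroc_trapezoid()]).
#' @param test `"wald"` (default) or `"lrt"` (likelihood ratio).
#' @return list with `p.value` (SCNP term), `coef` (fitted coefficients),
#'   `test`, and the fitted `model`.
#' @export
combined_independence_test <- function(scnp_scores, clinical_scores, outcomes,
                                       test = c("wald", "lrt")) {
  test <- match.arg(test)
  y <- as_binary_labels(outcomes)
  if (length(scnp_scores) != length(y) || length(clinical_scores) != length(y))
    stop("scores and outcomes must have equal length")
  keep <- stats::complete.cases(scnp_scores, clinical_scores, y)
  if (!all(keep)) stop("complete (scnp, clinical, outcome) triples required")
  if (stats::sd(scnp_scores) == 0 || stats::sd(clinical_scores) == 0 ||
      abs(stats::cor(scnp_scores, clinical_scores)) > 0.999)
    stop("scnp and clinical scores are collinear; combined model is not identifiable")
  dat <- data.frame(y = y, scnp = scnp_scores, clinical = clinical_scores)
  fit <- stats::glm(y ~ scnp + clinical, family = stats::binomial(), data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("combined model is rank deficient; scores may be collinear")
  p <- if (test == "wald") {
    stats::coef(summary(fit))["scnp", "Pr(>|z|)"]
  } else {
    fit0 <- stats::glm(y ~ clinical, family = stats::binomial(), data = dat)
    stats::pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  list(p.value = unname(p), coef = stats::coef(fit), test = test, model = fit)
}

#' Concordance of classifier scores between paired BM and PB samples
#'
#' For patients with both a bone-marrow and a peripheral-blood score, computes
#' the Pearson correlation and a per-patient concordance flag at the 0.5
#' probability midpoint (both scores on the same side).
#'
#' @param bm_scores,pb_scores named numeric vectors of classifier scores;
#'   names are patient ids and pairing is by name.
#' @return list with `r` (Pearson correlation), `n` (paired patients),
#'   `pairs` (data.frame: patient_id, bm, pb, concordant).
#' @export
paired_concordance <- function(bm_scores, pb_scores) {
  if (is.null(names(bm_scores)) || is.null(names(pb_scores)))
    stop("scores must be named by patient id")
  ids <- intersect(names(bm_scores), names(pb_scores))
  if (length(ids) < 3L) stop("fewer than 3 paired patients")
  bm <- unname(bm_scores[ids]); pb <- unname(pb_scores[ids])
  pairs <- data.frame(patient_id = ids, bm = bm, pb = pb,
                      concordant = (bm > 0.5) == (pb > 0.5),
                      stringsAsFactors = FALSE)
  list(r = stats::cor(bm, pb), n = length(ids), pairs = pairs)
}

#' Classifier performance within clinical subgroups
#'
#' Computes the AUROC with DeLong confidence intervals within subgroups of the
#' cohort. Numeric grouping variables (age, WBC) are dichotomized at their
#' median, with values equal to the median assigned to the lower
#' (`<= median`) subgroup. Unknown cytogenetic risk should be imputed to
#' intermediate before calling (see [impute_clinical()]). Subgroups lacking
#' either outcome class are flagged as not computable rather than scored.
#'
#' @inheritParams auroc_trapezoid
#' @param grouping a factor/character vector (used as is) or numeric vector
#'   (median split) defining subgroups; one entry per patient.
#' @param level confidence level for the DeLong intervals.
#' @return data.frame with one row per subgroup: `subgroup`, `n1`, `n0`,
#'   `auroc`, `lower`, `upper`, `computable`.
#' @export
subgroup_performance <- function(scores, labels, grouping, level = 0.95) {
  y <- as_binary_labels(labels)
  if (length(grouping) != length(y)) stop("grouping must match labels in length")
  if (is.numeric(grouping)) {
    med <- stats::median(grouping)
    grouping <- ifelse(grouping <= med,
                       sprintf("<=median (%.3g)", med),
                       sprintf(">median (%.3g)", med))
  }
  grouping <- as.character(grouping)
  out <- lapply(sort(unique(grouping)), function(g) {
    sel <- grouping == g
    n1 <- sum(y[sel] == 1L); n0 <- sum(y[sel] == 0L)
    if (n1 >= 2L && n0 >= 2L) {
      ci <- delong_ci(scores[sel], y[sel], level = level)
      data.frame(subgroup = g, n1 = n1, n0 = n0, auroc = ci$estimate,
                 lower = ci$lower, upper = ci$upper, computable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subgroup = g, n1 = n1, n0 = n0, auroc = NA_real_,
                 lower = NA_real_, upper = NA_real_, computable = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
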