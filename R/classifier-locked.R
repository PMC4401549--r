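#' The locked DX_SCNP classifier
#'
#' Loads the locked two-node response classifier from the JSON artifact
#' shipped with the package. The model is a logistic score on
#' hinge-squared transforms of two 24-hour apoptosis node metrics:
#'
#' * `N1` = scaled Mann-Whitney `Uu` of blast cPARP, AraC+Dauno 24 h vs
#'   untreated 24 h; `C1 = (N1 - 0.5)^2` if `N1 > 0.5`, else 0.
#' * `N2` = scaled `Uu` of blast CD34, AraC+Dauno 24 h vs untreated 24 h;
#'   `C2 = (0.5 - N2)^2` if `N2 < 0.5`, else 0.
#' * `score = plogis(-1.26004 + 95.60133 * C1 + 34.94358 * C2)`.
#'
#' Higher scores indicate a greater probability of response (CR/CRi). The
#' coefficients are locked: they are read from the artifact and never
#' refitted.
#'
#' @param path optional path to an alternative model artifact.
#' @return object of class `scnp_locked_model`.
#' @export
dx_scnp_model <- function(path = NULL) {
  path <- path %||% system.file("extdata", "locked_dxscnp.json", package = "scnpdx")
  if (path == "" || !file.exists(path)) stop("locked model artifact not found")
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(is.numeric(m$intercept), length(m$components) == 2L)
  class(m) <- "scnp_locked_model"
  m
}

#' @export
print.scnp_locked_model <- function(x, ...) {
  cat("<scnp_locked_model>", x$name, "v", x$version, "\n")
  cat(sprintf("  intercept %.5f\n", x$intercept))
  for (cp in x$components)
    cat(sprintf("  %s: %.5f * [%s]  (%s %gh %s %s)\n", cp$id, cp$coefficient,
                cp$transform, cp$node$modulator, cp$node$time_hr,
                cp$node$readout, cp$node$metric))
  invisible(x)
}

#' Score patients with the locked DX_SCNP classifier
#'
#' Evaluates the locked response score from the two 24-hour apoptosis node
#' metrics. Inputs are scaled Mann-Whitney Uu values and must lie in
#' `[0, 1]`; `NA` inputs yield `NA` scores (no-score). The score is
#' nondecreasing in `n1` (cPARP induction) and nonincreasing in `n2` (CD34
#' retention), and continuous across the hinge boundaries at 0.5.
#'
#' @param n1 Uu of AraC+Dauno 24 h blast cPARP vs untreated.
#' @param n2 Uu of AraC+Dauno 24 h blast CD34 vs untreated.
#' @param model a [dx_scnp_model()]; the shipped locked artifact by default.
#' @return numeric vector of response probabilities in `(0, 1)`.
#' @export
#' @examples
#' score_dx_scnp(0.5, 0.5)   # both hinge terms vanish: plogis(-1.26004)
#' score_dx_scnp(0.7, 0.3)
score_dx_scnp <- function(n1, n2, model = dx_scnp_model()) {
  stopifnot(inherits(model, "scnp_locked_model"))
  if (length(n1) != length(n2)) stop("n1 and n2 must have equal length")
  bad <- function(x) !is.na(x) & (x < 0 | x > 1)
  if (any(bad(n1)) || any(bad(n2)))
    stop("node metrics must lie in [0, 1] (scaled Mann-Whitney U values)")
  c1 <- ifelse(n1 > 0.5, (n1 - 0.5)^2, 0)
  c2 <- ifelse(n2 < 0.5, (0.5 - n2)^2, 0)
  co <- vapply(model$components, `[[`, numeric(1), "coefficient")
  lp <- model$intercept + co[1] * c1 + co[2] * c2
  stats::plogis(lp)
}

#' Apply the locked classifier to a node-metric table
#'
#' Extracts the two locked node metrics for every (patient, tissue) unit of a
#' node table and computes the DX_SCNP score. Units whose node metrics are
#' missing or non-evaluable receive no score, with the reason recorded
#' (mirrors the exclusion of patients lacking the classifier's node-metric
#' data).
#'
#' @param node_table output of [compute_node_table()].
#' @param model a [dx_scnp_model()].
#' @return data.frame: `patient_id`, `tissue`, `n1`, `n2`, `score`, `reason`
#'   (`NA` when scored).
#' @export
score_cohort <- function(node_table, model = dx_scnp_model()) {
  wide <- node_table_wide(node_table)
  f <- vapply(model$components, function(cp)
    node_feature_name(cp$node$modulator, cp$node$time_hr,
                      cp$node$readout, cp$node$metric), character(1))
  miss <- setdiff(f, names(wide))
  if (length(miss)) stop("node table lacks locked-model feature(s): ",
                         paste(miss, collapse = ", "))
  n1 <- wide[[f[1]]]; n2 <- wide[[f[2]]]
  score <- score_dx_scnp(n1, n2, model)
  reason <- ifelse(is.na(n1) | is.na(n2),
                   "missing or non-evaluable node metric", NA_character_)
  data.frame(patient_id = wide$patient_id, tissue = wide$tissue,
             n1 = n1, n2 = n2, score = score, reason = reason,
             stringsAsFactors = FALSE)
}
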