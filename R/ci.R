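#' Bias-corrected and accelerated (BCa) bootstrap CI for the AUROC
#'
#' Stratified bootstrap over patients within each outcome class, with the
#' bias-correction constant `z0` taken from the fraction of bootstrap AUROC
#' values below the point estimate and the acceleration constant `a` from the
#' jackknife skewness of the leave-one-out AUROC values.
#'
#' If the bootstrap distribution is degenerate (all resampled AUROC values
#' identical, as under perfect separation) or the bias correction is
#' undefined, the function falls back to the percentile interval with a
#' warning.
#'
#' @inheritParams auroc_trapezoid
#' @param B number of bootstrap resamples (at least 200).
#' @param level confidence level.
#' @param seed optional RNG seed.
#' @return list with `estimate`, `lower`, `upper`, `level`, `method`
#'   (`"bca"` or `"percentile"`), `B`.
#' @export
bca_ci <- function(scores, labels, B = 2000L, level = 0.95, seed = NULL) {
  if (B < 200L) stop("B must be at least 200")
  check_prob(level, "level")
  if (!is.null(seed)) set.seed(seed)
  y <- as_binary_labels(labels)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 patients per class")
  theta <- auroc_fast(pos, neg)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    boot[b] <- auroc_fast(pos[sample.int(n1, replace = TRUE)],
                          neg[sample.int(n0, replace = TRUE)])
  }
  alpha <- (1 - level) / 2
  pct <- function() {
    q <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
    list(estimate = theta, lower = max(0, q[1]), upper = min(1, q[2]),
         level = level, method = "percentile", B = B)
  }
  prop_below <- mean(boot < theta)
  if (stats::sd(boot) == 0 || prop_below <= 0 || prop_below >= 1) {
    warning("degenerate bootstrap AUROC distribution; percentile interval returned")
    return(pct())
  }
  z0 <- stats::qnorm(prop_below)
  # jackknife over all patients (both classes)
  jack <- c(
    vapply(seq_len(n1), function(i) auroc_fast(pos[-i], neg), numeric(1)),
    vapply(seq_len(n0), function(j) auroc_fast(pos, neg[-j]), numeric(1))
  )
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  a1 <- adj(zl); a2 <- adj(zu)
  if (!is.finite(a1) || !is.finite(a2) || a1 <= 0 || a2 >= 1 || a1 >= a2) {
    warning("BCa adjustment out of range; percentile interval returned")
    return(pct())
  }
  q <- stats::quantile(boot, c(a1, a2), names = FALSE, type = 7)
  list(estimate = theta, lower = max(0, q[1]), upper = min(1, q[2]),
       level = level, method = "bca", B = B)
}

# DeLong structural components: for each positive score the placement value
# against the negatives, and vice versa.
delong_components <- function(pos, neg) {
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUROC
#'
#' Wald-type interval based on the DeLong structural-component estimate of
#' the AUROC sampling variance. Because the AUROC is bounded, the interval is
#' constructed on the logit scale by default (delta method on
#' `qlogis(AUROC)`), which maintains near-nominal coverage at the cohort
#' sizes used here; `scale = "auc"` gives the plain Wald interval on the
#' AUROC scale, truncated to `[0, 1]`. Under perfect separation the variance
#' is zero and the (degenerate) point interval is flagged.
#'
#' @inheritParams auroc_trapezoid
#' @param level confidence level.
#' @param scale `"logit"` (default) or `"auc"` Wald scale.
#' @return list with `estimate`, `lower`, `upper`, `se` (AUROC scale),
#'   `level`, `degenerate` flag.
#' @export
delong_ci <- function(scores, labels, level = 0.95,
                      scale = c("logit", "auc")) {
  scale <- match.arg(scale)
  check_prob(level, "level")
  y <- as_binary_labels(labels)
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 patients per class")
  comp <- delong_components(pos, neg)
  theta <- mean(comp$v10)
  v <- stats::var(comp$v10) / length(pos) + stats::var(comp$v01) / length(neg)
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "logit" && se > 0 && theta > 0 && theta < 1) {
    se_l <- se / (theta * (1 - theta))
    lo <- stats::plogis(stats::qlogis(theta) - z * se_l)
    hi <- stats::plogis(stats::qlogis(theta) + z * se_l)
  } else {
    lo <- max(0, theta - z * se)
    hi <- min(1, theta + z * se)
  }
  list(estimate = theta, lower = lo, upper = hi,
       se = se, level = level, degenerate = (se == 0))
}
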