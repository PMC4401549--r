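#' Empirical AUROC by the trapezoidal rule
#'
#' Computes the area under the empirical ROC curve for a continuous (or tied)
#' score against binary outcome labels. The trapezoidal-rule area equals the
#' Mann-Whitney U statistic scaled by the number of discordant-pair
#' comparisons, `U / (n1 * n0)`, with tied score pairs contributing half
#' credit. Values above 0.5 indicate that the positive class (responders)
#' tends to score higher.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels binary outcome per score: logical, 0/1, or a two-level
#'   factor/character vector (responder class detected automatically, e.g.
#'   `"CR/CRi"` vs `"RD"`).
#' @return AUROC estimate in `[0, 1]`.
#' @seealso [exact_mw_test()] for the exact test of `AUROC = 0.5`,
#'   [bca_ci()] and [delong_ci()] for confidence intervals.
#' @export
#' @examples
#' auroc_trapezoid(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)) # 1: perfect separation
auroc_trapezoid <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(y)) stop("scores and labels must be complete")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both outcome classes must be present")
  scaled_u(scores[y == 1L], scores[y == 0L])
}

# Exact null distribution of the Mann-Whitney U statistic for sample sizes
# (m, n), no ties. Returns a numeric vector `counts` with counts[u + 1] =
# number of rank assignments giving U = u, u = 0..m*n. Counting recurrence:
#   N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1)
# Counts fit exactly in doubles for the sizes used here (choose(m+n, m) < 2^53).
mw_null_counts_env <- new.env(parent = emptyenv())

mw_null_counts <- function(m, n) {
  key <- paste0(m, "_", n)
  hit <- mw_null_counts_env[[key]]
  if (!is.null(hit)) return(hit)
  umax <- m * n
  # f[mm + 1, ] = counts over u for sample sizes (mm, nn), built up in nn
  f <- matrix(0, nrow = m + 1L, ncol = umax + 1L)
  f[, 1L] <- 1             # n' = 0: U identically 0 for any m'
  for (nn in seq_len(n)) {
    g <- matrix(0, nrow = m + 1L, ncol = umax + 1L)
    g[1L, 1L] <- 1
    for (mm in seq_len(m)) {
      # N(u; mm, nn) = N(u - nn; mm-1, nn) + N(u; mm, nn-1)
      shifted <- c(rep(0, nn), g[mm, seq_len(umax + 1L - nn)])
      g[mm + 1L, ] <- shifted + f[mm + 1L, ]
    }
    f <- g
  }
  counts <- f[m + 1L, ]
  mw_null_counts_env[[key]] <- counts
  counts
}

# P(U >= u) under the exact null for sizes (m, n)
mw_exact_tail <- function(u, m, n) {
  counts <- mw_null_counts(m, n)
  total <- sum(counts)
  sum(counts[seq.int(u + 1L, m * n + 1L)]) / total
}

#' Exact one-sided Mann-Whitney test of AUROC = 0.5
#'
#' Tests the null of no score/outcome association (`AUROC = 0.5`) against a
#' one-sided alternative, using the exact permutation null distribution of the
#' Mann-Whitney U statistic. For tie-free scores the null distribution is
#' computed by a dynamic-programming count over rank assignments; when ties
#' are present an exact count is unavailable and a Monte Carlo permutation
#' null (`nperm` draws, midrank U) is substituted.
#'
#' @inheritParams auroc_trapezoid
#' @param alternative `"greater"` (default; responders score higher,
#'   AUROC > 0.5) or `"less"`.
#' @param nperm permutation draws used when scores contain ties.
#' @return list with elements `auroc`, `u` (unscaled statistic), `p.value`,
#'   `method` (`"exact-dp"` or `"permutation"`), `n1`, `n0`.
#' @export
exact_mw_test <- function(scores, labels, alternative = c("greater", "less"),
                          nperm = 10000L) {
  alternative <- match.arg(alternative)
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  auc <- scaled_u(scores[y == 1L], scores[y == 0L])
  u <- auc * n1 * n0
  if (alternative == "less") { u <- n1 * n0 - u }
  if (!has_ties(scores[y == 1L], scores[y == 0L])) {
    p <- mw_exact_tail(as.integer(round(u)), n1, n0)
    method <- "exact-dp"
  } else {
    obs <- u
    ge <- 0L
    for (b in seq_len(nperm)) {
      yp <- sample(y)
      ub <- scaled_u(scores[yp == 1L], scores[yp == 0L]) * n1 * n0
      if (alternative == "less") ub <- n1 * n0 - ub
      if (ub >= obs - 1e-12) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + nperm)
    method <- "permutation"
  }
  list(auroc = auc, u = auc * n1 * n0, p.value = p, method = method,
       n1 = n1, n0 = n0, alternative = alternative)
}

#' Power of the exact AUROC test by binormal simulation
#'
#' Estimates the power of the one-sided exact Mann-Whitney test of
#' `H0: AUROC = 0.5` versus `H1: AUROC > 0.5` for a prospective validation
#' cohort, by simulating classifier scores from the binormal model: responder
#' scores `N(mu, 1)` and non-responder scores `N(0, 1)` with
#' `mu = sqrt(2) * qnorm(true_auroc)`, which gives the requested population
#' AUROC.
#'
#' @param n_total cohort size.
#' @param response_rate expected responder fraction; the responder count is
#'   `round(n_total * response_rate)`.
#' @param true_auroc population AUROC under the alternative, in (0.5, 1).
#' @param alpha one-sided significance level.
#' @param reps number of simulated cohorts.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `power` (rejection fraction), `reps`, `n1`, `n0`,
#'   `alpha`, `true_auroc`.
#' @export
#' @examples
#' power_simulation(n_total = 50, response_rate = 0.72, true_auroc = 0.75,
#'                  reps = 200, seed = 1)$power
power_simulation <- function(n_total, response_rate, true_auroc,
                             alpha = 0.05, reps = 2000L, seed = NULL) {
  check_prob(response_rate, "response_rate")
  if (!is.numeric(true_auroc) || true_auroc <= 0.5 || true_auroc >= 1)
    stop("true_auroc must lie in (0.5, 1)")
  if (!is.null(seed)) set.seed(seed)
  n1 <- as.integer(round(n_total * response_rate))
  n0 <- as.integer(n_total - n1)
  if (n1 < 1L || n0 < 1L) stop("both classes must be nonempty")
  mu <- sqrt(2) * stats::qnorm(true_auroc)
  # precompute exact tail probabilities once: continuous scores are tie-free
  counts <- mw_null_counts(n1, n0)
  tail_p <- rev(cumsum(rev(counts))) / sum(counts)  # tail_p[u+1] = P(U >= u)
  reject <- 0L
  for (r in seq_len(reps)) {
    pos <- stats::rnorm(n1, mean = mu)
    neg <- stats::rnorm(n0)
    u <- as.integer(round(scaled_u(pos, neg) * n1 * n0))
    if (tail_p[u + 1L] <= alpha) reject <- reject + 1L
  }
  list(power = reject / reps, reps = reps, n1 = n1, n0 = n0,
       alpha = alpha, true_auroc = true_auroc)
}
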