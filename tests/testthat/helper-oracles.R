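# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pairwise counting, full enumeration
# of label assignments, and literal transcriptions of formulas.

# AUROC as the mean over all (positive, negative) pairs of win + half-tie
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact one-sided Mann-Whitney p-value by full enumeration of all
# choose(n, n1) label assignments (tie-free scores)
oracle_mw_pvalue <- function(scores, labels) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  obs <- oracle_auroc(scores, labels) * n1 * n0
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) {
    yy <- integer(n); yy[idx] <- 1L
    oracle_auroc(scores, yy) * n1 * n0
  })
  mean(us >= obs - 1e-9)
}

# DeLong placement-value variance, written out with explicit loops
oracle_delong_var <- function(pos, neg) {
  v10 <- sapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)))
  v01 <- sapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)))
  stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
}

# binormal scores at a given population AUROC
binormal_scores <- function(n1, n0, auroc) {
  mu <- sqrt(2) * qnorm(auroc)
  list(scores = c(rnorm(n1, mu), rnorm(n0)),
       labels = c(rep(1L, n1), rep(0L, n0)))
}

# small single-tissue cohort config for pipeline tests
small_config <- function(n = 20, events = 800, seed = 1,
                         tissue_prob = c(BM = 1, PB = 0), ...) {
  scnp_sim_config(n_patients = n, mean_events = events,
                  tissue_prob = tissue_prob, seed = seed, ...)
}

# the apoptosis panel subset (3 wells per unit) for fast simulations
apoptosis_panel <- function() {
  p <- default_node_panel()
  p[p$modulator == "AraC+Dauno" & p$readout %in% c("cPARP", "CD34"), ]
}

cparp_feature <- "AraC+Dauno|24|cPARP|Uu"
cd34_feature <- "AraC+Dauno|24|CD34|Uu"

# wide feature matrix + responder outcome from a cohort
cohort_features <- function(coh) {
  nt <- compute_node_table(coh)
  wide <- node_table_wide(nt)
  outcome <- coh$patients$outcome[match(wide$patient_id,
                                        coh$patients$patient_id)]
  keep <- outcome %in% c("CR", "CRi", "RD")
  list(X = wide[keep, setdiff(names(wide), c("patient_id", "tissue")),
                drop = FALSE],
       y = as.integer(outcome[keep] %in% c("CR", "CRi")),
       wide = wide, node_table = nt, keep = keep)
}
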