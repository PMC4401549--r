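#' Default gating parameters
#'
#' Parameters of the four-level gating hierarchy. The scatter "intact" gate
#' is a rectangular region between per-well quantile bounds on FSC and SSC;
#' the viability gate thresholds the Amine Aqua channel at the 98th
#' percentile of an unstained (autofluorescence) reference; the blast gate
#' selects the CD45-dim cluster among viable cells (a deterministic 1-D
#' 2-means split on log10 CD45, falling back to all viable cells when the
#' cluster centers are closer than `cd45_min_sep` log10 units) with an SSC
#' upper bound. A quantile-window CD45 mode is available as an alternative.
#'
#' @param intact_q lower/upper quantile bounds of the scatter gate.
#' @param aqua_q reference percentile for the viability threshold.
#' @param cd45_mode `"cluster"` or `"quantile"`.
#' @param cd45_min_sep minimum log10 separation of the CD45 cluster centers
#'   for the split to be applied.
#' @param cd45_q CD45 quantile window (quantile mode).
#' @param ssc_blast_q SSC upper-quantile bound within viable cells.
#' @return named list of gate parameters.
#' @export
gate_defaults <- function(intact_q = c(0.02, 0.98), aqua_q = 0.98,
                          cd45_mode = c("cluster", "quantile"),
                          cd45_min_sep = 0.4, cd45_q = c(0, 0.98),
                          ssc_blast_q = 0.98) {
  list(intact_q = intact_q, aqua_q = aqua_q,
       cd45_mode = match.arg(cd45_mode), cd45_min_sep = cd45_min_sep,
       cd45_q = cd45_q, ssc_blast_q = ssc_blast_q)
}

# deterministic 1-D 2-means: optimal split of sorted values minimizing
# within-cluster sum of squares; returns centers and the midpoint boundary
two_means_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L) return(list(centers = c(xs[1], xs[1]), split = xs[1]))
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kbest <- which.min(ss_left + ss_right)
  c1 <- cs[kbest] / kbest
  c2 <- (cs[n] - cs[kbest]) / (n - kbest)
  list(centers = c(c1, c2), split = (c1 + c2) / 2)
}

#' Compute the viability threshold from an unstained reference well
#'
#' The 98th percentile (type-7 interpolation) of the Amine Aqua channel of an
#' autofluorescence/unstained reference, mirroring the cPARP split rule.
#'
#' @param reference_aqua Amine Aqua intensities of the reference well
#'   (typically its intact cells).
#' @param q percentile to use.
#' @return threshold value.
#' @export
viability_threshold <- function(reference_aqua, q = 0.98) {
  if (length(reference_aqua) == 0L) stop("empty viability reference")
  stats::quantile(reference_aqua, q, names = FALSE, type = 7)
}

#' Apply the hierarchical gating to one well
#'
#' Identifies the nested cell populations: intact cells by scatter, viable
#' cells by Amine Aqua below the viability threshold, blast cells by
#' CD45-dim/SSC-low among viable cells, and optionally cPARP-negative
#' (healthy) blasts when a cPARP split point is supplied (see
#' [cparp_negative_gate()]). Masks are nested by construction:
#' healthy_blast ⊆ blast ⊆ viable ⊆ intact.
#'
#' @param events an [scnp_events()] table with FSC, SSC, AquaAmine and CD45
#'   channels (gating operates on the raw scale).
#' @param params gate parameters from [gate_defaults()].
#' @param aqua_threshold viability threshold from [viability_threshold()].
#' @param cparp_split optional cPARP positive/negative split point; when
#'   supplied (and the well carries a cPARP channel) the healthy-blast mask
#'   is populated.
#' @return object of class `scnp_gates`: logical masks `intact`, `viable`,
#'   `blast`, `healthy_blast` over events, plus `counts`.
#' @export
gate_hierarchy <- function(events, params = gate_defaults(), aqua_threshold,
                           cparp_split = NULL) {
  d <- events$data
  need <- c("FSC", "SSC", "AquaAmine", "CD45")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing gating channel(s): ", paste(miss, collapse = ", "))
  n <- nrow(d)
  empty <- function() {
    z <- rep(FALSE, n)
    structure(list(intact = z, viable = z, blast = z, healthy_blast = z,
                   counts = c(intact = 0L, viable = 0L, blast = 0L,
                              healthy_blast = 0L)),
              class = "scnp_gates")
  }
  if (n == 0L) { warning("empty well"); return(empty()) }
  qf <- stats::quantile(d$FSC, params$intact_q, names = FALSE, type = 7)
  qs <- stats::quantile(d$SSC, params$intact_q, names = FALSE, type = 7)
  intact <- d$FSC >= qf[1] & d$FSC <= qf[2] & d$SSC >= qs[1] & d$SSC <= qs[2]
  if (!any(intact)) { warning("empty intact gate"); return(empty()) }
  viable <- intact & d$AquaAmine <= aqua_threshold
  blast <- viable
  if (any(viable)) {
    ssc_cap <- stats::quantile(d$SSC[viable], params$ssc_blast_q,
                               names = FALSE, type = 7)
    if (params$cd45_mode == "cluster") {
      km <- two_means_1d(log10(pmax(d$CD45[viable], .Machine$double.xmin)))
      cd45_ok <- if (abs(diff(km$centers)) < params$cd45_min_sep) {
        rep(TRUE, n)                         # single population: all viable
      } else {
        log10(pmax(d$CD45, .Machine$double.xmin)) <= km$split  # dim cluster
      }
    } else {
      qc <- stats::quantile(d$CD45[viable], params$cd45_q, names = FALSE, type = 7)
      cd45_ok <- d$CD45 >= qc[1] & d$CD45 <= qc[2]
    }
    blast <- viable & cd45_ok & d$SSC <= ssc_cap
  }
  healthy <- rep(FALSE, n)
  if (!is.null(cparp_split) && "cPARP" %in% names(d))
    healthy <- blast & d$cPARP <= cparp_split
  structure(list(intact = intact, viable = viable, blast = blast,
                 healthy_blast = healthy,
                 counts = c(intact = sum(intact), viable = sum(viable),
                            blast = sum(blast), healthy_blast = sum(healthy))),
            class = "scnp_gates")
}

#' cPARP positive/negative split and healthy-cell mask
#'
#' The split point is the 98th percentile (type-7 linear interpolation) of
#' the autofluorescence well's cPARP values; blast cells at or below the
#' split are cPARP-negative ("healthy", non-apoptotic). The fraction of
#' blast cells passing this gate, times 100, is the PhIntact metric.
#'
#' @param blast_events_cparp cPARP intensities of gated blast cells.
#' @param autofluorescence_cparp cPARP intensities of the autofluorescence
#'   well (must be nonempty; there is no fallback threshold).
#' @return list with `mask` (logical over blast events) and `split_point`.
#' @export
cparp_negative_gate <- function(blast_events_cparp, autofluorescence_cparp) {
  if (length(autofluorescence_cparp) == 0L)
    stop("autofluorescence well is empty; cPARP split undefined")
  split <- stats::quantile(autofluorescence_cparp, 0.98, names = FALSE, type = 7)
  list(mask = blast_events_cparp <= split, split_point = split)
}
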