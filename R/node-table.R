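#' Compute the per-patient node-metric table
#'
#' Runs the full per-well processing for every patient-tissue unit of a
#' simulated (or assembled) cohort: per-plate ERF calibration from the bead
#' plates, hierarchical gating on raw intensities, and metric computation on
#' ERF-calibrated values. Produces one record per
#' (patient, tissue, node, metric) with an evaluability flag.
#'
#' Population conventions: short-term signaling nodes are computed on
#' cPARP-negative (healthy) blasts, using the autofluorescence well's blast
#' cPARP 98th percentile as the split; 24-hour apoptosis nodes
#' (AraC+Dauno to cPARP / CD34) are computed on total viable blasts — without
#' the cPARP-negative restriction, since the induced cPARP shift is the
#' signal — with the 24-hour untreated well as the unmodulated reference.
#' The viability-loss node is computed on intact cells. A record is flagged
#' non-evaluable when a required well is missing or any population used
#' falls below `min_cells`.
#'
#' @param cohort an [simulate_cohort()] object (or a list with `units`,
#'   `wells`, `beads`, `panel`).
#' @param panel node panel; defaults to the cohort's own panel.
#' @param gates gating parameters from [gate_defaults()].
#' @param min_cells evaluability threshold on the gated populations used.
#' @param calibrate logical; apply bead ERF calibration before computing
#'   metrics (gating always operates on raw values).
#' @param location location statistic for the ratio metrics.
#' @return data.frame of class `scnp_node_table` with columns `patient_id`,
#'   `tissue`, `modulator`, `time_hr`, `readout`, `metric`, `value`,
#'   `n_cells`, `evaluable`.
#' @export
compute_node_table <- function(cohort, panel = NULL, gates = gate_defaults(),
                               min_cells = 200L, calibrate = TRUE,
                               location = "median") {
  panel <- panel %||% cohort$panel
  cal_by_plate <- if (calibrate) lapply(cohort$beads, fit_erf_calibration) else NULL

  wkey <- function(p, t, m, h) paste(p, t, m, h, sep = "|")
  well_index <- stats::setNames(
    seq_along(cohort$wells),
    vapply(cohort$wells, function(w)
      wkey(w$patient_id, w$tissue, w$modulator, w$time_hr), character(1)))
  get_well <- function(p, t, m, h) {
    i <- well_index[wkey(p, t, m, h)]
    if (is.na(i)) NULL else cohort$wells[[i]]
  }

  recs <- vector("list", nrow(cohort$units) * nrow(panel))
  ridx <- 0L
  push <- function(pid, tis, nd, value, n_cells, evaluable) {
    ridx <<- ridx + 1L
    recs[[ridx]] <<- data.frame(
      patient_id = pid, tissue = tis, modulator = nd$modulator,
      time_hr = nd$time_hr, readout = nd$readout, metric = nd$metric,
      value = value, n_cells = n_cells, evaluable = evaluable,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(cohort$units))) {
    pid <- cohort$units$patient_id[i]; tis <- cohort$units$tissue[i]
    # per-unit context: autofluorescence references and gated/calibrated wells
    auto <- get_well(pid, tis, "autofluorescence", 0.25)
    ctx <- new.env(parent = emptyenv())  # cache of processed wells
    aqua_thr <- NULL; auto_cparp <- NULL; cparp_split <- NULL; auto_cal <- NULL
    if (!is.null(auto)) {
      g0 <- suppressWarnings(gate_hierarchy(auto, gates,
                                            aqua_threshold = Inf))
      aqua_thr <- tryCatch(
        viability_threshold(auto$data$AquaAmine[g0$intact], gates$aqua_q),
        error = function(e) NULL)
      auto_gates <- suppressWarnings(
        gate_hierarchy(auto, gates, aqua_threshold = aqua_thr %||% Inf))
      auto_cparp <- auto$data$cPARP[auto_gates$blast]
      if (length(auto_cparp)) {
        cparp_split <- cparp_negative_gate(auto_cparp, auto_cparp)$split_point
        auto_gates <- suppressWarnings(
          gate_hierarchy(auto, gates, aqua_threshold = aqua_thr %||% Inf,
                         cparp_split = cparp_split))
      }
      auto_cal <- if (calibrate)
        apply_calibration(auto, cal_by_plate[[auto$plate]]) else auto
      assign("auto", list(well = auto, cal = auto_cal, gates = auto_gates), ctx)
    }
    processed <- function(m, h) {
      key <- paste(m, h, sep = "@")
      hit <- ctx[[key]]
      if (!is.null(hit)) return(hit)
      w <- get_well(pid, tis, m, h)
      if (is.null(w)) return(NULL)
      gh <- suppressWarnings(gate_hierarchy(w, gates,
                                            aqua_threshold = aqua_thr %||% Inf,
                                            cparp_split = cparp_split))
      cw <- if (calibrate) apply_calibration(w, cal_by_plate[[w$plate]]) else w
      out <- list(well = w, cal = cw, gates = gh)
      ctx[[key]] <- out
      out
    }
    pop_values <- function(pw, channel, population) {
      mask <- pw$gates[[population]]
      pw$cal$data[[channel]][mask]
    }

    for (j in seq_len(nrow(panel))) {
      nd <- panel[j, ]
      mwell <- processed(nd$modulator, nd$time_hr)
      uwell <- if (nd$modulator == "unmodulated") mwell
               else processed("unmodulated", nd$time_hr)
      need_auto <- nd$metric %in% c("Ua", "Basal", "PhIntact", "PctPos")
      if (is.null(mwell) || (nd$metric %in% c("Uu", "log2Fold") && is.null(uwell)) ||
          (need_auto && is.null(auto)) || is.null(aqua_thr)) {
        push(pid, tis, nd, NA_real_, 0L, FALSE)
        next
      }
      m_vals <- pop_values(mwell, nd$readout, nd$population)
      res <- tryCatch({
        switch(nd$metric,
          Uu = {
            u_vals <- pop_values(uwell, nd$readout, nd$population)
            list(v = metric_uu(m_vals, u_vals),
                 n = min(length(m_vals), length(u_vals)))
          },
          log2Fold = {
            u_vals <- pop_values(uwell, nd$readout, nd$population)
            list(v = metric_log2fold(m_vals, u_vals, location),
                 n = min(length(m_vals), length(u_vals)))
          },
          Ua = {
            a_vals <- pop_values(ctx$auto, nd$readout, nd$population)
            list(v = metric_ua(m_vals, a_vals),
                 n = min(length(m_vals), length(a_vals)))
          },
          Basal = {
            a_vals <- pop_values(ctx$auto, nd$readout, nd$population)
            list(v = metric_basal(m_vals, a_vals, location),
                 n = min(length(m_vals), length(a_vals)))
          },
          PhIntact = {
            # scale-free count metric: computed on raw values with the raw split
            bl <- mwell$well$data[[nd$readout]][mwell$gates$blast]
            list(v = metric_phintact(bl, auto_cparp),
                 n = length(bl))
          },
          PctPos = {
            bl <- mwell$well$data[[nd$readout]][mwell$gates[[nd$population]]]
            a_raw <- ctx$auto$well$data[[nd$readout]][ctx$auto$gates[[nd$population]]]
            list(v = metric_pctpos(bl, a_raw), n = length(bl))
          },
          stop("unknown metric: ", nd$metric))
      }, error = function(e) NULL)
      if (is.null(res) || !is.finite(res$v)) {
        push(pid, tis, nd, NA_real_, 0L, FALSE)
      } else {
        push(pid, tis, nd, res$v, as.integer(res$n), res$n >= min_cells)
      }
    }
  }
  out <- do.call(rbind, recs[seq_len(ridx)])
  key <- with(out, paste(patient_id, tissue, modulator, time_hr, readout, metric))
  if (anyDuplicated(key)) stop("duplicate node-metric records")
  out <- out[order(out$patient_id, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scnp_node_table", "data.frame")
  out
}

#' Pivot a node-metric table to a wide feature matrix
#'
#' One row per (patient, tissue), one column per node-metric feature named
#' `modulator|time|readout|metric`. Non-evaluable records become `NA`.
#'
#' @param node_table output of [compute_node_table()].
#' @return data.frame with `patient_id`, `tissue` and one numeric column per
#'   feature.
#' @export
node_table_wide <- function(node_table) {
  nt <- node_table
  nt$value[!nt$evaluable] <- NA_real_
  feat <- with(nt, paste(modulator, time_hr, readout, metric, sep = "|"))
  unit <- with(nt, paste(patient_id, tissue, sep = "|"))
  units <- unique(unit)
  feats <- unique(feat)
  m <- matrix(NA_real_, nrow = length(units), ncol = length(feats),
              dimnames = list(units, feats))
  m[cbind(match(unit, units), match(feat, feats))] <- nt$value
  parts <- strsplit(units, "|", fixed = TRUE)
  out <- data.frame(patient_id = vapply(parts, `[`, character(1), 1L),
                    tissue = vapply(parts, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m, check.names = FALSE))
}

#' Name of a node-metric feature column
#'
#' @param modulator,time_hr,readout,metric node coordinates.
#' @return the `modulator|time|readout|metric` column name used by
#'   [node_table_wide()].
#' @export
node_feature_name <- function(modulator, time_hr, readout, metric) {
  paste(modulator, time_hr, readout, metric, sep = "|")
}
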