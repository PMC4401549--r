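#' Fit an ERF calibration from an 8-peak rainbow-bead plate
#'
#' For each fluorescence channel, fits a least-squares line through the
#' (log10 median peak intensity, log10 manufacturer-assigned reference ERF)
#' pairs. The line is stored in the orientation
#' `log10(intensity) = intercept + slope * log10(ERF)`, so a plate whose
#' intensities are exactly `g` times the reference values fits slope 1 and
#' intercept `log10(g)`. Peaks with nonpositive or saturated medians are
#' excluded; at least `min_peaks` resolvable peaks are required.
#'
#' @param beads an [simulate_beads()] object (or any list with
#'   `reference_erf` and `channels`, the latter a per-channel list of 8 peak
#'   intensity vectors).
#' @param min_peaks minimum resolvable peaks per channel.
#' @param saturation intensity above which a peak median is treated as
#'   saturated and excluded (default `Inf`: no exclusion).
#' @return object of class `scnp_calibration`: a data.frame with one row per
#'   channel (`channel`, `slope`, `intercept`, `r_squared`, `n_peaks`) and a
#'   `plate` attribute.
#' @export
fit_erf_calibration <- function(beads, min_peaks = 3L, saturation = Inf) {
  ref <- beads$reference_erf
  if (length(ref) != 8L) stop("expected 8 bead peaks")
  rows <- lapply(names(beads$channels), function(ch) {
    med <- vapply(beads$channels[[ch]], stats::median, numeric(1))
    use <- is.finite(med) & med > 0 & med < saturation
    if (sum(use) < min_peaks)
      stop(sprintf("channel %s: only %d resolvable peaks (< %d)",
                   ch, sum(use), min_peaks))
    x <- log10(ref[use]); yv <- log10(med[use])
    fit <- stats::lm(yv ~ x)
    co <- stats::coef(fit)
    if (co[2] <= 0) stop(sprintf("channel %s: nonpositive calibration slope", ch))
    data.frame(channel = ch, slope = unname(co[2]), intercept = unname(co[1]),
               r_squared = stats::cor(x, yv)^2, n_peaks = sum(use),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "plate") <- beads$plate %||% NA
  class(out) <- c("scnp_calibration", "data.frame")
  out
}

#' Serialize an ERF calibration to JSON
#'
#' Writes (or reads back) a fitted calibration with its plate id and fit
#' diagnostics, so per-plate calibrations can be stored alongside exported
#' event tables.
#'
#' @param cal an [fit_erf_calibration()] object.
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the `scnp_calibration` object.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "scnp_calibration"))
  jsonlite::write_json(
    list(plate = attr(cal, "plate"),
         channels = as.data.frame(unclass(cal), stringsAsFactors = FALSE)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- m$channels
  if (is.null(out$channel) || is.null(out$slope))
    stop("malformed calibration JSON: ", path)
  attr(out, "plate") <- m$plate
  class(out) <- c("scnp_calibration", "data.frame")
  out
}

#' Apply an ERF calibration to an event table
#'
#' Maps each fluorescence channel from raw intensity to Equivalent Reference
#' Fluorophores by inverting the channel's calibration line:
#' `ERF = 10^((log10(I) - intercept) / slope)`. Scatter channels (FSC, SSC)
#' pass through unchanged. The mapping is strictly increasing, so within-well
#' rank order is preserved. An event table containing a fluorescence channel
#' not covered by the calibration is an error.
#'
#' @param events an [scnp_events()] table on the raw scale.
#' @param cal an [fit_erf_calibration()] object.
#' @return the event table with fluorescence channels on the ERF scale
#'   (`$scale == "ERF"`).
#' @export
apply_calibration <- function(events, cal) {
  stopifnot(inherits(events, "scnp_events"), inherits(cal, "scnp_calibration"))
  if (identical(events$scale, "ERF")) stop("events already on the ERF scale")
  fluor <- setdiff(names(events$data), c("FSC", "SSC"))
  missing_ch <- setdiff(fluor, cal$channel)
  if (length(missing_ch))
    stop("uncalibrated channel(s): ", paste(missing_ch, collapse = ", "))
  for (ch in fluor) {
    i <- match(ch, cal$channel)
    x <- pmax(events$data[[ch]], .Machine$double.xmin)
    events$data[[ch]] <- 10^((log10(x) - cal$intercept[i]) / cal$slope[i])
  }
  events$scale <- "ERF"
  events
}
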