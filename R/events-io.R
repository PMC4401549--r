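#' Write and read single-well event tables
#'
#' Two dialects are supported:
#'
#' * `"csv"`: a plain-text table with header `event_index,<channel>,...`
#'   (UTF-8, `.` decimal) plus a JSON sidecar `<path>.json` holding the well
#'   metadata (well id, patient, tissue, modulator, time, plate, scale).
#'   Round-trips values exactly (full double precision).
#' * `"fcs3"`: a minimal FCS 3.0 file (list-mode, float32 data, little
#'   endian) with metadata stored as TEXT keywords. Round-trips values to
#'   float32 precision.
#'
#' @param events an [scnp_events()] table.
#' @param path output file path.
#' @param dialect `"csv"` or `"fcs3"`.
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   [scnp_events()] object.
#' @export
write_events <- function(events, path, dialect = c("csv", "fcs3")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(events, "scnp_events"))
  if (dialect == "csv") write_events_csv(events, path) else write_events_fcs(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, dialect = c("csv", "fcs3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") read_events_csv(path) else read_events_fcs(path)
}

events_meta <- function(events) {
  list(well_id = events$well_id, patient_id = events$patient_id,
       tissue = events$tissue, modulator = events$modulator,
       time_hr = events$time_hr, plate = events$plate, scale = events$scale)
}

write_events_csv <- function(events, path) {
  d <- events$data
  out <- cbind(data.frame(event_index = seq_len(nrow(d))), d)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(events_meta(events), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
}

read_events_csv <- function(path) {
  d <- tryCatch(utils::read.csv(path, check.names = FALSE),
                error = function(e) stop("malformed CSV at ", path, ": ",
                                         conditionMessage(e)))
  if (!"event_index" %in% names(d))
    stop("malformed CSV at ", path, " line 1: missing 'event_index' header")
  d$event_index <- NULL
  mpath <- paste0(path, ".json")
  if (!file.exists(mpath)) stop("missing metadata sidecar: ", mpath)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  scnp_events(d, well_id = m$well_id, patient_id = m$patient_id,
              tissue = m$tissue, modulator = m$modulator,
              time_hr = as.numeric(m$time_hr),
              plate = as.integer(m$plate %||% NA_integer_),
              scale = m$scale %||% "raw")
}

# ---- minimal FCS 3.0 (list mode, $DATATYPE F, little endian) --------------

write_events_fcs <- function(events, path) {
  d <- events$data
  p <- ncol(d); n <- nrow(d)
  delim <- "/"
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(p), "$TOT", as.character(n),
          "$NEXTDATA", "0")
  for (i in seq_len(p)) {
    rng <- if (n > 0) max(d[[i]]) else 1
    kw <- c(kw, sprintf("$P%dN", i), names(d)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(rng) + 1, scientific = FALSE))
  }
  m <- events_meta(events)
  kw <- c(kw, "WELLID", m$well_id, "PATIENTID", m$patient_id,
          "TISSUE", m$tissue, "MODULATOR", m$modulator,
          "TIMEHR", format(m$time_hr), "PLATE", format(m$plate),
          "SCALE", m$scale)
  text <- paste0(delim, paste(kw, collapse = delim), delim)
  header_len <- 58L
  text_beg <- header_len
  text_end <- text_beg + nchar(text, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- if (n > 0) data_beg + 4L * n * p - 1L else 0L
  if (n == 0) data_beg <- 0L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (n > 0) {
    # events are interleaved row-by-row (list mode)
    vals <- as.numeric(t(as.matrix(d)))
    writeBin(vals, con, size = 4L, endian = "little")
  }
}

read_events_fcs <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 58L || rawToChar(raw[1:6]) != "FCS3.0")
    stop("malformed FCS at ", path, " offset 0: bad magic")
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  text <- rawToChar(raw[(text_beg + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0)
    stop("malformed FCS at ", path, " offset ", text_beg, ": odd keyword count")
  kv <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  p <- as.integer(kv[["$PAR"]]); n <- as.integer(kv[["$TOT"]])
  if (!identical(kv[["$DATATYPE"]], "F"))
    stop("unsupported FCS datatype: ", kv[["$DATATYPE"]])
  chans <- vapply(seq_len(p), function(i) kv[[sprintf("$P%dN", i)]], character(1))
  if (n > 0) {
    vals <- readBin(raw[(data_beg + 1):(data_end + 1)], what = "numeric",
                    size = 4L, n = n * p, endian = "little")
    mat <- matrix(vals, ncol = p, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), ncol = p)
  }
  d <- as.data.frame(mat)
  names(d) <- chans
  scnp_events(d, well_id = kv[["WELLID"]], patient_id = kv[["PATIENTID"]],
              tissue = kv[["TISSUE"]], modulator = kv[["MODULATOR"]],
              time_hr = as.numeric(kv[["TIMEHR"]]),
              plate = suppressWarnings(as.integer(kv[["PLATE"]])),
              scale = kv[["SCALE"]])
}
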