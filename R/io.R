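# Plain-text recording and analysis-output files.
#
# Recording file dialect (bit-exact, diffable):
#   '#'-prefixed header lines:   #key=value
#   column declaration:          #COLUMNS<TAB>time<TAB>position_um<TAB>sise1...
#   event marks:                 #EVENT<TAB>time_s<TAB>free text
#   then tab-separated data rows with fixed decimal formatting
#   (time and position to 4 decimals, voltages to 6 decimals).
# UTF-8, LF line endings. The position column stores scan-axis displacement in
# um (0 = position 0), never absolute manipulator coordinates.

RECORDING_CHANNELS <- c("sise1", "sise2", "volt1", "volt2")

#' Construct a recording
#'
#' A uniformly sampled multichannel electrode recording: a data frame of
#' samples, a key-value metadata header and a list of timestamped event
#' marks.
#'
#' @param samples Data frame with columns `time` (s, strictly increasing,
#'   uniform), `position_um` (scan-axis displacement, um) and voltage channels
#'   `sise1` (mV; mandatory) plus optional `sise2`, `volt1`, `volt2`.
#' @param meta Named list of scalar metadata (acquisition parameters, file
#'   name, ...). Values must be atomic scalars.
#' @param events Data frame with columns `time` (s) and `text`, or `NULL`.
#' @return An object of class `sise_recording`.
#' @export
recording <- function(samples, meta = list(), events = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("time", "position_um", "sise1") %in% names(samples)))
  keep <- c("time", "position_um",
            intersect(RECORDING_CHANNELS, names(samples)))
  samples <- samples[, keep, drop = FALSE]
  dt <- diff(samples$time)
  if (nrow(samples) > 1) {
    if (any(dt <= 0)) {
      stop("recording time must be strictly increasing (first violation at row ",
           which(dt <= 0)[1] + 1, ")", call. = FALSE)
    }
    med <- stats::median(dt)
    if (any(abs(dt - med) > med)) {
      stop("recording time must be uniform to within one sample interval",
           call. = FALSE)
    }
  }
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), text = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(events), all(c("time", "text") %in% names(events)))
  events <- events[order(events$time), c("time", "text"), drop = FALSE]
  rownames(events) <- NULL
  rownames(samples) <- NULL
  structure(list(meta = meta, samples = samples, events = events),
            class = "sise_recording")
}

#' @export
print.sise_recording <- function(x, ...) {
  chans <- intersect(RECORDING_CHANNELS, names(x$samples))
  cat(sprintf("<recording>  %d samples, %.1f s, channels: %s, %d event mark(s)\n",
              nrow(x$samples), diff(range(x$samples$time)),
              paste(chans, collapse = ", "), nrow(x$events)))
  invisible(x)
}

active_channels <- function(rec) {
  intersect(RECORDING_CHANNELS, names(rec$samples))
}

format_meta_value <- function(v) {
  if (is.logical(v)) {
    if (v) "TRUE" else "FALSE"
  } else if (is.numeric(v)) {
    sprintf("%.10g", v)
  } else {
    as.character(v)
  }
}

#' Write a recording to a plain-text file
#'
#' Writes the documented dialect: `#key=value` header lines, `#COLUMNS` and
#' `#EVENT` lines, then tab-separated data rows with fixed decimal
#' formatting, so that writing the same recording twice produces
#' byte-identical files.
#'
#' @param rec A `sise_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sise_recording"))
  cols <- c("time", "position_um", active_channels(rec))
  hdr <- character(0)
  if (length(rec$meta)) {
    hdr <- sprintf("#%s=%s", names(rec$meta),
                   vapply(rec$meta, format_meta_value, character(1)))
  }
  hdr <- c(hdr, paste0("#COLUMNS\t", paste(cols, collapse = "\t")))
  if (nrow(rec$events)) {
    hdr <- c(hdr, sprintf("#EVENT\t%.4f\t%s", rec$events$time,
                          rec$events$text))
  }
  fmt <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)
  body <- do.call(paste, c(lapply(cols, function(cn) {
    fmt(rec$samples[[cn]], if (cn %in% c("time", "position_um")) 4L else 6L)
  }), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a recording from a plain-text file
#'
#' Parses the dialect written by [write_recording()] and validates the
#' recording invariants (strictly increasing, uniform time base).
#'
#' @param path File path.
#' @return A `sise_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  if (any(is_hdr[-seq_len(n_hdr)])) {
    bad <- which(is_hdr & seq_along(lines) > n_hdr)[1]
    stop("malformed recording: header line after data at line ", bad,
         call. = FALSE)
  }
  hdr <- lines[seq_len(n_hdr)]
  cols <- NULL
  meta <- list()
  ev_time <- numeric(0); ev_text <- character(0)
  for (i in seq_along(hdr)) {
    h <- sub("^#", "", hdr[i])
    if (startsWith(h, "COLUMNS\t")) {
      cols <- strsplit(h, "\t", fixed = TRUE)[[1]][-1]
    } else if (startsWith(h, "EVENT\t")) {
      parts <- strsplit(h, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) {
        stop("malformed #EVENT line at line ", i, call. = FALSE)
      }
      ev_time <- c(ev_time, as.numeric(parts[2]))
      ev_text <- c(ev_text, paste(parts[-(1:2)], collapse = "\t"))
    } else {
      eq <- regexpr("=", h, fixed = TRUE)
      if (eq < 1) stop("malformed header line at line ", i, call. = FALSE)
      key <- substr(h, 1, eq - 1)
      val <- substr(h, eq + 1, nchar(h))
      meta[[key]] <- utils::type.convert(val, as.is = TRUE)
    }
  }
  if (is.null(cols)) {
    stop("malformed recording: missing #COLUMNS header", call. = FALSE)
  }
  if (!all(c("time", "position_um", "sise1") %in% cols)) {
    stop("recording is missing mandatory columns (time, position_um, sise1)",
         call. = FALSE)
  }
  data_lines <- lines[!is_hdr]
  if (!length(data_lines)) stop("recording has no data rows", call. = FALSE)
  samples <- utils::read.table(text = data_lines, sep = "\t",
                               col.names = cols, colClasses = "numeric")
  dt <- diff(samples$time)
  if (any(dt <= 0)) {
    stop("non-monotonic time at line ", n_hdr + which(dt <= 0)[1] + 1L,
         call. = FALSE)
  }
  recording(samples, meta = meta,
            events = data.frame(time = ev_time, text = ev_text,
                                stringsAsFactors = FALSE))
}

# Canonical analysis-output column order; at most 15 may be present.
ANALYSIS_COLUMNS <- c(
  "time_min", "position_index",
  "V1_mV", "dV1_mV", "conc1_mM", "flux1_nmol_m2_s", "flux1_buffercorr",
  "V2_mV", "dV2_mV", "conc2_mM", "flux2_nmol_m2_s", "flux2_buffercorr",
  "volt1_mV", "volt2_mV", "event_mark")

#' Write an analysis output table
#'
#' Tab-separated text with one header row. Columns follow the fixed canonical
#' order (`time_min, position_index, V1_mV, dV1_mV, conc1_mM,
#' flux1_nmol_m2_s, flux1_buffercorr, V2_mV, ..., volt1_mV, volt2_mV,
#' event_mark`); absent optional columns are omitted, never blank-filled, and
#' at most 15 columns are ever written.
#'
#' @param out A data frame whose columns are a subset of the canonical set,
#'   e.g. from [analyse_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_analysis <- function(out, path) {
  stopifnot(is.data.frame(out))
  if (!all(names(out) %in% ANALYSIS_COLUMNS)) {
    stop("unknown analysis columns: ",
         paste(setdiff(names(out), ANALYSIS_COLUMNS), collapse = ", "),
         call. = FALSE)
  }
  out <- out[, ANALYSIS_COLUMNS[ANALYSIS_COLUMNS %in% names(out)],
             drop = FALSE]
  stopifnot(ncol(out) <= 15)
  txt <- vapply(names(out), function(cn) {
    x <- out[[cn]]
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.6g", x))
    else as.character(x)
  }, character(nrow(out)))
  if (nrow(out) == 1) txt <- matrix(txt, nrow = 1)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               apply(txt, 1, paste, collapse = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
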