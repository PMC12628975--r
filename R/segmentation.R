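# Split a recording into position loops using the recorded position channel
# (robust to timing jitter between instrument versions), not nominal loop
# arithmetic.

#' Split a recording into position segments
#'
#' Partitions the samples into runs of constant electrode position and tags
#' each run with its position index (0 = near the tissue, 1 = at
#' `scan_distance`). Samples are assigned to the level (0 or
#' `scan_distance`) they lie within 10% of `scan_distance` of; transition
#' samples strictly between the two levels are assigned to the following
#' segment. A final segment shorter than the loop duration is flagged
#' `truncated` (it is excluded from dV analysis); segments overlapping an
#' event mark whose text starts with `"reposition"` are flagged
#' `spans_reposition`.
#'
#' @param rec A `sise_recording`.
#' @param acq An [acquisition_config()]; defaults to one rebuilt from the
#'   recording's metadata.
#' @return A list of `position_segment` objects (class `segment_list`). Each
#'   segment holds `index`, `position_index`, a samples data frame with
#'   absolute `time`, `local_time` (starting at 0) and the voltage channels,
#'   and the flags `truncated` and `spans_reposition`.
#' @export
segment_recording <- function(rec, acq = acquisition_from_meta(rec$meta)) {
  stopifnot(inherits(rec, "sise_recording"),
            inherits(acq, "acquisition_config"))
  pos <- rec$samples$position_um
  scan_um <- acq$scan_distance * 1e6
  tol <- 0.1 * scan_um
  lev <- rep(NA_integer_, length(pos))
  lev[abs(pos) <= tol] <- 0L
  lev[abs(pos - scan_um) <= tol] <- 1L
  if (anyNA(lev)) {
    if (mean(is.na(lev)) > 0.02) {
      stop("segmentation error: position values do not cluster at two ",
           "levels (0 and ", scan_um, " um)", call. = FALSE)
    }
    # transition samples join the following segment (backward fill)
    filled <- rev(cummax_na(rev(lev)))
    lev <- ifelse(is.na(lev), filled, lev)
    if (anyNA(lev)) {  # trailing transition samples join the last segment
      last <- max(which(!is.na(lev)))
      lev[is.na(lev)] <- lev[last]
    }
  }
  runs <- rle(lev)
  n_runs <- length(runs$lengths)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  durations <- runs$lengths * acq$sample_interval
  if (n_runs > 1 &&
      any(durations[-n_runs] < acq$loop_duration / 2)) {
    stop("segmentation error: position oscillates faster than half the ",
         "loop duration", call. = FALSE)
  }
  repos <- rec$events$time[grepl("^reposition", rec$events$text,
                                 ignore.case = TRUE)]
  chans <- active_channels(rec)
  segs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    sl <- starts[k]:ends[k]
    s <- rec$samples[sl, c("time", chans), drop = FALSE]
    s$local_time <- s$time - s$time[1]
    s <- s[, c("time", "local_time", chans)]
    rownames(s) <- NULL
    truncated <- k == n_runs &&
      durations[k] < acq$loop_duration - acq$sample_interval / 2
    spans <- length(repos) > 0 &&
      any(repos >= s$time[1] & repos <= s$time[nrow(s)])
    segs[[k]] <- structure(
      list(index = k, position_index = runs$values[k], samples = s,
           truncated = truncated, spans_reposition = spans),
      class = "position_segment")
  }
  structure(segs, class = "segment_list")
}

# running "last seen value" that skips NAs (helper for backward fill)
cummax_na <- function(x) {
  out <- x
  last <- NA_integer_
  for (i in seq_along(x)) {
    if (!is.na(x[i])) last <- x[i]
    out[i] <- last
  }
  out
}

#' @export
print.segment_list <- function(x, ...) {
  cat(sprintf("<segments>  %d position loop(s): [%s]\n", length(x),
              paste(vapply(x, function(s) s$position_index, integer(1)),
                    collapse = ",")))
  invisible(x)
}

segment_usable <- function(seg) {
  !seg$truncated && !seg$spans_reposition
}
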