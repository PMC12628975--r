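# Drift-corrected voltage difference between the two electrode positions.
#
# The self-referencing correction: fit one least-squares line through the
# settled samples of two flanking loops at the same position, then a second
# line with the *same* slope through the settled samples of the loop in
# between (at the other position). The vertical offset between the parallel
# lines is the drift-corrected dV; any linear drift is absorbed by the shared
# slope and cancels exactly.

#' Mean settled voltage of one segment
#'
#' Arithmetic mean of a voltage channel over the samples recorded after the
#' `start_fit` settling time within the loop.
#'
#' @param seg A `position_segment`.
#' @param start_fit Settling time in seconds (segment-local).
#' @param channel Channel name, e.g. `"sise1"`.
#' @return Mean voltage in mV.
#' @export
segment_voltage <- function(seg, start_fit = 5, channel = "sise1") {
  stopifnot(inherits(seg, "position_segment"),
            channel %in% names(seg$samples))
  sel <- seg$samples$local_time >= start_fit
  if (!any(sel)) {
    stop("segment ", seg$index, " has no samples at or after start_fit = ",
         start_fit, " s", call. = FALSE)
  }
  mean(seg$samples[[channel]][sel])
}

#' Drift-corrected dV from three consecutive loops
#'
#' `prev` and `next` must be at the same position, `mid` at the other. An
#' ordinary least-squares line in absolute time is fitted through the pooled
#' settled samples of `prev` and `next`; a parallel line (same slope) is then
#' placed through the settled samples of `mid`. The y-offset between the two
#' lines, signed so that `dV = V(position 0) - V(position 1)`, is the
#' drift-corrected voltage difference.
#'
#' @param prev,mid,nxt Three consecutive `position_segment`s.
#' @param start_fit Settling time in seconds.
#' @param channel Channel name.
#' @return An object of class `dv_estimate`: list with `center_index`,
#'   `time` (midpoint of the middle loop, s), `dv` (mV), fitted voltages
#'   `V0`/`V1` (each parallel line evaluated at `time`, mV), the shared
#'   `slope` (mV/s) and `n_points_used`.
#' @export
dv_triple <- function(prev, mid, nxt, start_fit = 5, channel = "sise1") {
  for (s in list(prev, mid, nxt)) {
    stopifnot(inherits(s, "position_segment"))
    if (!segment_usable(s)) {
      stop("segment ", s$index, " is flagged ",
           if (s$truncated) "truncated" else "spans_reposition",
           call. = FALSE)
    }
  }
  if (prev$position_index != nxt$position_index ||
      prev$position_index == mid$position_index) {
    stop("segments ", prev$index, ",", mid$index, ",", nxt$index,
         " do not alternate positions", call. = FALSE)
  }
  pick <- function(seg) {
    sel <- seg$samples$local_time >= start_fit
    if (sum(sel) < 2) {
      stop("segment ", seg$index, " has fewer than 2 samples after ",
           "start_fit = ", start_fit, " s", call. = FALSE)
    }
    seg$samples[sel, c("time", channel)]
  }
  outer <- rbind(pick(prev), pick(nxt))
  inner <- pick(mid)
  t_o <- outer$time;  v_o <- outer[[channel]]
  t_i <- inner$time;  v_i <- inner[[channel]]

  # centered OLS keeps full double precision at large absolute times
  tc <- t_o - mean(t_o)
  b <- sum(tc * v_o) / sum(tc^2)
  te <- (mid$samples$time[1] + mid$samples$time[nrow(mid$samples)]) / 2
  v_outer_at <- mean(v_o) + b * (te - mean(t_o))
  v_inner_at <- mean(v_i) + b * (te - mean(t_i))
  offset <- v_outer_at - v_inner_at
  dv <- if (mid$position_index == 1) offset else -offset
  if (!is.finite(dv)) stop("non-finite dV estimate", call. = FALSE)
  if (mid$position_index == 1) {
    V0 <- v_outer_at; V1 <- v_inner_at
  } else {
    V0 <- v_inner_at; V1 <- v_outer_at
  }
  structure(list(center_index = mid$index, time = te, dv = dv,
                 V0 = V0, V1 = V1, slope = b,
                 n_points_used = length(t_o) + length(t_i)),
            class = "dv_estimate")
}

#' Drift-corrected dV series over a whole recording
#'
#' Slides a window of three consecutive loops over the segment list and
#' computes one [dv_triple()] estimate centered on each interior segment; the
#' first and last segments yield no estimate. Triples that violate the
#' preconditions (flagged segments, non-alternating positions, no settled
#' samples) are skipped and reported.
#'
#' @param segments A `segment_list` from [segment_recording()].
#' @param start_fit Settling time in seconds.
#' @param channel Channel name.
#' @return A data frame with one row per estimate (`center_index`, `time`,
#'   `dv_mV`, `V0_mV`, `V1_mV`, `slope_mV_s`, `n_points`); skipped triples
#'   are recorded in the `"skipped"` attribute as a data frame
#'   `(center_index, reason)`.
#' @export
dv_series <- function(segments, start_fit = 5, channel = "sise1") {
  stopifnot(inherits(segments, "segment_list"))
  usable <- Filter(segment_usable, segments)
  empty <- data.frame(center_index = integer(0), time = numeric(0),
                      dv_mV = numeric(0), V0_mV = numeric(0),
                      V1_mV = numeric(0), slope_mV_s = numeric(0),
                      n_points = integer(0))
  if (length(usable) < 3) {
    warning("fewer than 3 usable segments: empty dV series")
    attr(empty, "skipped") <- data.frame(center_index = integer(0),
                                         reason = character(0))
    return(empty)
  }
  rows <- list()
  skipped <- list()
  for (i in seq(2L, length(usable) - 1L)) {
    est <- tryCatch(
      dv_triple(usable[[i - 1]], usable[[i]], usable[[i + 1]],
                start_fit = start_fit, channel = channel),
      error = function(e) conditionMessage(e))
    if (inherits(est, "dv_estimate")) {
      rows[[length(rows) + 1L]] <- data.frame(
        center_index = est$center_index, time = est$time, dv_mV = est$dv,
        V0_mV = est$V0, V1_mV = est$V1, slope_mV_s = est$slope,
        n_points = est$n_points_used)
    } else {
      skipped[[length(skipped) + 1L]] <- data.frame(
        center_index = usable[[i]]$index, reason = est)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(center_index = integer(0), reason = character(0))
  }
  out
}
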