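# Full analysis pipeline: recording -> segments -> drift-corrected dV ->
# concentrations -> fluxes -> analysis-output table.

#' Analyse a recording into concentrations and fluxes
#'
#' Runs the complete pipeline: split the recording into position loops,
#' compute the drift-corrected dV series for each ion-selective channel,
#' convert the per-loop mean voltages into concentrations (the alternating
#' position-0/position-1 concentration trace), and convert each dV estimate
#' into a flux with the configured method, optionally buffer-corrected.
#' One output row is produced per position loop; loops without a dV estimate
#' (the first and last, plus any skipped triple) carry `NA` in the dV and
#' flux columns.
#'
#' @param rec A `sise_recording`.
#' @param cal A `sise_calibration` for channel `sise1`.
#' @param cfg A [flux_config()].
#' @param start_fit Settling time override in seconds; defaults to the value
#'   stored in the recording metadata (the stored raw data are never
#'   modified by this choice).
#' @param cal2 Calibration for channel `sise2`; required when that channel is
#'   present in the recording.
#' @return A data frame (class `sise_analysis`) whose columns follow the
#'   fixed canonical order used by [write_analysis()]: always `time_min`,
#'   `position_index`, `V1_mV`, `dV1_mV`, `conc1_mM`, `flux1_nmol_m2_s`;
#'   plus `flux1_buffercorr` under buffer correction, the channel-2 block
#'   when `sise2` is present, per-loop means of the auxiliary voltage
#'   channels, and `event_mark` when the recording contains event marks
#'   (at most 15 columns). Skipped triples are reported in the `"skipped"`
#'   attribute.
#' @export
analyse_recording <- function(rec, cal, cfg, start_fit = NULL, cal2 = NULL) {
  stopifnot(inherits(rec, "sise_recording"),
            inherits(cal, "sise_calibration"),
            inherits(cfg, "flux_config"))
  acq <- acquisition_from_meta(rec$meta)
  if (is.null(start_fit)) start_fit <- acq$start_fit
  chans <- active_channels(rec)
  if ("sise2" %in% chans && is.null(cal2)) {
    stop("recording has an active sise2 channel: cal2 is required",
         call. = FALSE)
  }
  segs <- segment_recording(rec, acq)
  n_seg <- length(segs)
  seg_mid <- vapply(segs, function(s) {
    (s$samples$time[1] + s$samples$time[nrow(s$samples)]) / 2
  }, numeric(1))
  out <- data.frame(
    time_min = seg_mid / 60,
    position_index = vapply(segs, function(s) s$position_index, integer(1)))

  seg_mean <- function(channel) {
    vapply(segs, function(s) {
      tryCatch(segment_voltage(s, start_fit, channel),
               error = function(e) NA_real_)
    }, numeric(1))
  }

  skipped <- list()
  analyse_channel <- function(channel, chan_cal) {
    V <- seg_mean(channel)
    conc <- voltage_to_concentration(chan_cal, V)
    dvs <- dv_series(segs, start_fit = start_fit, channel = channel)
    skipped[[channel]] <<- attr(dvs, "skipped")
    dv_col <- rep(NA_real_, n_seg)
    flux <- rep(NA_real_, n_seg)
    flux_bc <- rep(NA_real_, n_seg)
    for (k in seq_len(nrow(dvs))) {
      i <- dvs$center_index[k]
      est <- structure(list(center_index = i, time = dvs$time[k],
                            dv = dvs$dv_mV[k], V0 = dvs$V0_mV[k],
                            V1 = dvs$V1_mV[k], slope = dvs$slope_mV_s[k],
                            n_points_used = dvs$n_points[k]),
                       class = "dv_estimate")
      J <- if (cfg$method == "chemical_potential") {
        flux_chemical_potential(est, cfg, chan_cal)
      } else {
        flux_diffusion_gradient(est, cfg, chan_cal)
      }
      dv_col[i] <- est$dv
      flux[i] <- J
      if (!is.null(cfg$buffer)) {
        flux_bc[i] <- if (cfg$method == "chemical_potential") {
          r <- buffer_ratio(cfg$buffer$species, cfg$buffer$conc_mM,
                            cfg$buffer$pH)
          correct_flux_chemical(J, r)
        } else {
          c0 <- voltage_to_concentration(chan_cal, est$V0)
          c1 <- voltage_to_concentration(chan_cal, est$V1)
          # pH from the measured H+ concentration (mM -> molar)
          correct_flux_fick(J, cfg$buffer$species, cfg$buffer$conc_mM,
                            pH0 = 3 - log10(c0), pH1 = 3 - log10(c1),
                            dx = cfg$dx)
        }
      }
    }
    list(V = V, dv = dv_col, conc = conc,
         flux = flux * 1e9, flux_bc = flux_bc * 1e9)
  }

  ch1 <- analyse_channel("sise1", cal)
  out$V1_mV <- ch1$V
  out$dV1_mV <- ch1$dv
  out$conc1_mM <- ch1$conc
  out$flux1_nmol_m2_s <- ch1$flux
  if (!is.null(cfg$buffer)) out$flux1_buffercorr <- ch1$flux_bc
  if ("sise2" %in% chans) {
    ch2 <- analyse_channel("sise2", cal2)
    out$V2_mV <- ch2$V
    out$dV2_mV <- ch2$dv
    out$conc2_mM <- ch2$conc
    out$flux2_nmol_m2_s <- ch2$flux
    if (!is.null(cfg$buffer)) out$flux2_buffercorr <- ch2$flux_bc
  }
  if ("volt1" %in% chans) out$volt1_mV <- seg_mean("volt1")
  if ("volt2" %in% chans) out$volt2_mV <- seg_mean("volt2")
  if (nrow(rec$events)) {
    out$event_mark <- vapply(segs, function(s) {
      t0 <- s$samples$time[1]
      t1 <- s$samples$time[nrow(s$samples)]
      hits <- rec$events$text[rec$events$time >= t0 & rec$events$time <= t1]
      paste(hits, collapse = "; ")
    }, character(1))
  }
  out <- out[, ANALYSIS_COLUMNS[ANALYSIS_COLUMNS %in% names(out)],
             drop = FALSE]
  attr(out, "skipped") <- skipped
  class(out) <- c("sise_analysis", "data.frame")
  out
}
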