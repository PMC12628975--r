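# Acquisition timing/geometry configuration shared by the simulator,
# segmentation and flux modules.

#' Acquisition configuration
#'
#' Timing and scan parameters of a self-referencing electrode measurement.
#' Defaults reproduce the standard instrument settings: 10 ms sampling, 10 s
#' position loops (1000 samples per loop), 50 um horizontal scan distance,
#' and a 5 s settling window before the fit (`start_fit`).
#'
#' @param sample_interval Sampling interval in seconds.
#' @param loop_duration Dwell time at one position in seconds.
#' @param scan_distance Electrode travel between positions 0 and 1, in metres.
#' @param scan_angle Angle of electrode movement above horizontal, degrees
#'   (0 = horizontal); only the normal component `scan_distance * cos(angle)`
#'   changes the distance to the tissue.
#' @param manipulator_side `"left"` or `"right"`; which side of the tissue the
#'   manipulator sits on. Affects only the physical direction of travel, never
#'   the stored displacement column.
#' @param start_fit Within-loop time (s) after which the electrode response is
#'   treated as settled; only later samples enter the regressions.
#' @param sise2,volt1,volt2 Logical flags: record a second ion-selective
#'   channel and/or up to two auxiliary voltage channels.
#' @return An object of class `acquisition_config`. `n_samples_per_loop` is
#'   derived as `round(loop_duration / sample_interval)`.
#' @examples
#' acquisition_config()  # 1000 samples of 10 ms per 10 s loop
#' @export
acquisition_config <- function(sample_interval = 0.01,
                               loop_duration = 10,
                               scan_distance = 50e-6,
                               scan_angle = 0,
                               manipulator_side = c("right", "left"),
                               start_fit = 5,
                               sise2 = FALSE, volt1 = FALSE, volt2 = FALSE) {
  manipulator_side <- match.arg(manipulator_side)
  stopifnot(sample_interval > 0, loop_duration > 0, scan_distance > 0,
            scan_angle >= 0, scan_angle < 90,
            start_fit >= 0, start_fit < loop_duration,
            is.logical(sise2), is.logical(volt1), is.logical(volt2))
  n <- as.integer(round(loop_duration / sample_interval))
  if (abs(n * sample_interval - loop_duration) > 1e-9 * loop_duration) {
    stop("loop_duration must be an integer multiple of sample_interval",
         call. = FALSE)
  }
  structure(list(sample_interval = sample_interval,
                 loop_duration = loop_duration,
                 n_samples_per_loop = n,
                 scan_distance = scan_distance,
                 scan_angle = scan_angle,
                 manipulator_side = manipulator_side,
                 start_fit = start_fit,
                 sise2 = sise2, volt1 = volt1, volt2 = volt2),
            class = "acquisition_config")
}

#' Tissue geometry specification
#'
#' Shape and size of the studied tissue or cell, used to correct the electrode
#' travel distance so fluxes are referenced to the tissue surface.
#'
#' @param shape `"flat"`, `"cylinder"` (e.g. a root) or `"sphere"` (e.g. an
#'   oocyte or protoplast).
#' @param radius Tissue radius in metres; required for cylinder and sphere.
#' @param gap0 Distance from the tissue surface to electrode position 0, in
#'   metres.
#' @return An object of class `geometry_spec`.
#' @examples
#' geometry_spec("cylinder", radius = 50e-6, gap0 = 50e-6)
#' @export
geometry_spec <- function(shape = c("flat", "cylinder", "sphere"),
                          radius = NULL, gap0 = 50e-6) {
  shape <- match.arg(shape)
  stopifnot(gap0 >= 0)
  if (shape != "flat") {
    if (is.null(radius) || !is.numeric(radius) || radius <= 0) {
      stop("geometry '", shape, "' requires a positive tissue radius",
           call. = FALSE)
    }
  }
  structure(list(shape = shape, radius = radius, gap0 = gap0),
            class = "geometry_spec")
}

#' Rebuild an acquisition configuration from recording metadata
#'
#' Recordings written by the simulator (and the documented file dialect)
#' carry their acquisition parameters in the metadata header; missing keys
#' fall back to the instrument defaults.
#'
#' @param meta Named list, e.g. `rec$meta`.
#' @return An [acquisition_config()].
#' @export
acquisition_from_meta <- function(meta) {
  g <- function(key, default) {
    if (!is.null(meta[[key]])) meta[[key]] else default
  }
  acquisition_config(
    sample_interval = g("sample_interval_s", 0.01),
    loop_duration = g("loop_duration_s", 10),
    scan_distance = g("scan_distance_um", 50) * 1e-6,
    scan_angle = g("scan_angle_deg", 0),
    manipulator_side = g("manipulator_side", "right"),
    start_fit = g("start_fit_s", 5),
    sise2 = isTRUE(g("sise2", FALSE)),
    volt1 = isTRUE(g("volt1", FALSE)),
    volt2 = isTRUE(g("volt2", FALSE)))
}
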