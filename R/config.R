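# YAML configuration files for the command-line interface. All lengths are
# given in um, concentrations in mM and fluxes in nmol m^-2 s^-1 in the
# files; they are converted to SI internally.

geometry_from_list <- function(g) {
  if (is.null(g)) return(geometry_spec("flat"))
  geometry_spec(shape = if (is.null(g$shape)) "flat" else g$shape,
                radius = if (is.null(g$radius_um)) NULL else g$radius_um * 1e-6,
                gap0 = if (is.null(g$gap0_um)) 50e-6 else g$gap0_um * 1e-6)
}

#' Read a simulation scenario file
#'
#' YAML file with top-level keys `ion`, `bulk_conc_mM`,
#' `true_flux_nmol_m2_s` (a number, or a list of `{time_s, flux_nmol_m2_s}`
#' steps), `electrode` (`slope_mV_per_decade`, `intercept_mV`, `tau_s`,
#' `drift_mV_min`, `noise_sd_mV`), `acquisition` (`sample_interval_s`,
#' `loop_duration_s`, `scan_distance_um`, `scan_angle_deg`,
#' `manipulator_side`, `start_fit_s`, `sise2`, `volt1`, `volt2`), `geometry`
#' (`shape`, `radius_um`, `gap0_um`), `unstirred_layer_um`, `n_loops` and
#' `seed`. Missing keys fall back to the defaults of
#' [simulation_scenario()].
#'
#' @param path YAML file path.
#' @return A [simulation_scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(x, default) if (is.null(x)) default else x
  a <- g(y$acquisition, list())
  acq <- acquisition_config(
    sample_interval = g(a$sample_interval_s, 0.01),
    loop_duration = g(a$loop_duration_s, 10),
    scan_distance = g(a$scan_distance_um, 50) * 1e-6,
    scan_angle = g(a$scan_angle_deg, 0),
    manipulator_side = g(a$manipulator_side, "right"),
    start_fit = g(a$start_fit_s, 5),
    sise2 = isTRUE(a$sise2), volt1 = isTRUE(a$volt1),
    volt2 = isTRUE(a$volt2))
  e <- g(y$electrode, list())
  electrode <- list(slope = g(e$slope_mV_per_decade, 58),
                    intercept = g(e$intercept_mV, 0),
                    tau = g(e$tau_s, 0.5),
                    drift = g(e$drift_mV_min, 0),
                    noise_sd = g(e$noise_sd_mV, 0.03))
  tf <- g(y$true_flux_nmol_m2_s, 0)
  true_flux <- if (is.list(tf)) {
    data.frame(time = vapply(tf, function(s) s$time_s, numeric(1)),
               flux = vapply(tf, function(s) s$flux_nmol_m2_s,
                             numeric(1)) * 1e-9)
  } else {
    tf * 1e-9
  }
  simulation_scenario(
    ion = g(y$ion, "K+"),
    bulk_conc = g(y$bulk_conc_mM, 0.5),
    true_flux = true_flux,
    electrode = electrode,
    acquisition = acq,
    geometry = geometry_from_list(y$geometry),
    unstirred_layer = g(y$unstirred_layer_um, 500) * 1e-6,
    n_loops = g(y$n_loops, 6),
    seed = g(y$seed, 1))
}

#' Read a flux-analysis configuration file
#'
#' YAML file with keys `method`, `ion`, `bath_conc_mM`,
#' `use_position1_conc`, `geometry` (`shape`, `radius_um`, `gap0_um`),
#' `scan` (`distance_um`, `angle_deg`), `start_fit_s` and optional `buffer`
#' (`name`, `conc_mM`, `pH`). Scan parameters omitted from the file are
#' taken from the recording metadata at analysis time.
#'
#' @param path YAML file path.
#' @param meta Optional recording metadata used to fill in scan defaults.
#' @return A list with components `cfg` (a [flux_config()]) and `start_fit`
#'   (seconds, or `NULL` to use the recording's stored value).
#' @export
read_analysis_config <- function(path, meta = NULL) {
  y <- yaml::read_yaml(path)
  g <- function(x, default) if (is.null(x)) default else x
  m <- function(key, default) {
    if (!is.null(meta[[key]])) meta[[key]] else default
  }
  scan <- g(y$scan, list())
  buffer <- y$buffer
  cfg <- flux_config(
    method = g(y$method, "chemical_potential"),
    ion = g(y$ion, "K+"),
    bath_conc = y$bath_conc_mM,
    use_position1_conc = isTRUE(y$use_position1_conc),
    geometry = geometry_from_list(y$geometry),
    scan_distance = g(scan$distance_um, m("scan_distance_um", 50)) * 1e-6,
    scan_angle = g(scan$angle_deg, m("scan_angle_deg", 0)),
    buffer = buffer)
  list(cfg = cfg, start_fit = y$start_fit_s)
}
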