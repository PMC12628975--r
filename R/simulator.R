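# Physics-based simulator: synthetic self-referencing electrode recordings
# over a steady-state diffusion field with known ground-truth flux.
#
# Model: the tissue surface emits a (piecewise-constant) source flux into an
# unstirred layer of thickness L in which transport is purely diffusive; the
# field is quasi-static (it tracks flux changes instantly). The electrode
# reports the Nernstian voltage of the local concentration through a
# first-order lag, plus linear drift and i.i.d. Gaussian noise.

#' Simulation scenario
#'
#' Everything needed to generate a synthetic recording with known ground
#' truth. Defaults reflect a typical K+ measurement: 0.5 mM bath, ideal
#' 58 mV/decade electrode, 0.5 s response time constant, 0.03 mV noise (the
#' system noise floor of a good A/D chain) and a 500 um unstirred layer.
#'
#' @param ion Ion name or `ion_species`.
#' @param bulk_conc Bath concentration beyond the unstirred layer, in mM
#'   (= mol m^-3).
#' @param true_flux Source flux at the tissue surface in mol m^-2 s^-1,
#'   positive = efflux from the tissue. Either a single number or a data
#'   frame `(time, flux)` defining a piecewise-constant J(t) (each flux value
#'   applies from its `time` onward; the first `time` must be 0).
#' @param electrode List with `slope` (mV/decade, signed), `intercept` (mV at
#'   1 mM), `tau` (response time constant, s), `drift` (mV/min) and
#'   `noise_sd` (mV).
#' @param acquisition An [acquisition_config()].
#' @param geometry A [geometry_spec()]; `gap0` is the surface-to-position-0
#'   distance.
#' @param unstirred_layer Thickness L of the diffusive layer, metres.
#' @param n_loops Number of position loops (>= 3 so at least one
#'   drift-corrected dV can be formed).
#' @param seed Integer seed for the noise generator.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(ion = "K+",
                                bulk_conc = 0.5,
                                true_flux = 0,
                                electrode = list(),
                                acquisition = acquisition_config(),
                                geometry = geometry_spec("flat", gap0 = 50e-6),
                                unstirred_layer = 500e-6,
                                n_loops = 6,
                                seed = 1L) {
  el <- utils::modifyList(list(slope = 58, intercept = 0, tau = 0.5,
                               drift = 0, noise_sd = 0.03), electrode)
  stopifnot(inherits(acquisition, "acquisition_config"),
            inherits(geometry, "geometry_spec"),
            bulk_conc > 0, el$tau >= 0, el$noise_sd >= 0, el$slope != 0,
            unstirred_layer > 0, n_loops >= 3)
  if (is.data.frame(true_flux)) {
    stopifnot(all(c("time", "flux") %in% names(true_flux)),
              nrow(true_flux) >= 1, true_flux$time[1] <= 0,
              !is.unsorted(true_flux$time, strictly = TRUE))
  } else {
    stopifnot(is.numeric(true_flux), length(true_flux) == 1)
  }
  structure(list(ion = ion_species(ion), bulk_conc = bulk_conc,
                 true_flux = true_flux, electrode = el,
                 acquisition = acquisition, geometry = geometry,
                 unstirred_layer = unstirred_layer,
                 n_loops = as.integer(n_loops), seed = as.integer(seed)),
            class = "simulation_scenario")
}

flux_at_time <- function(true_flux, t) {
  if (is.data.frame(true_flux)) {
    idx <- findInterval(t, true_flux$time)
    true_flux$flux[pmax(idx, 1L)]
  } else {
    rep_len(true_flux, length(t))
  }
}

#' Electrode position waveform
#'
#' Scan-axis displacement (um) for a run of `n_loops` position loops. The
#' electrode stays at position 0 for the whole first loop and then alternates
#' between position 1 (`scan_distance`) and position 0, moving instantaneously
#' at loop boundaries.
#'
#' @param acq An [acquisition_config()].
#' @param n_loops Number of loops.
#' @return Numeric vector of length `n_loops * n_samples_per_loop`, in um.
#' @export
position_waveform <- function(acq, n_loops) {
  stopifnot(inherits(acq, "acquisition_config"), n_loops >= 1)
  loop_level <- ifelse(seq_len(n_loops) %% 2 == 0, acq$scan_distance * 1e6, 0)
  rep(loop_level, each = acq$n_samples_per_loop)
}

#' Steady-state concentration field around a source
#'
#' Concentration at a given distance from the tissue surface when the surface
#' emits flux `J_surface` into an unstirred layer of thickness `L`, beyond
#' which the bath is perfectly mixed at `bulk`. Closed forms per geometry
#' (distance x from the surface, a = tissue radius, r = a + x, R = a + L):
#' flat `c = bulk + (J/D)(L - x)`; cylinder `c = bulk + (J a / D) ln(R/r)`;
#' sphere `c = bulk + (J a^2 / D)(1/r - 1/R)`. All reduce to `bulk` when
#' `J = 0` or beyond the layer.
#'
#' @param geom A [geometry_spec()].
#' @param ion Ion name or `ion_species` (sets the diffusion coefficient).
#' @param bulk Bulk concentration, mM (= mol m^-3).
#' @param J_surface Source flux at the surface, mol m^-2 s^-1, positive =
#'   efflux.
#' @param distance Distance(s) from the tissue surface, metres (>= 0).
#' @param L Unstirred-layer thickness, metres.
#' @return Concentration(s) in mM.
#' @export
concentration_field <- function(geom, ion, bulk, J_surface, distance,
                                L = 500e-6) {
  stopifnot(inherits(geom, "geometry_spec"), all(distance >= 0), L > 0)
  D <- diffusion_coefficient(ion)
  x <- pmin(distance, L)
  conc <- switch(geom$shape,
    flat = bulk + (J_surface / D) * (L - x),
    cylinder = {
      a <- geom$radius; r <- a + x; R <- a + L
      bulk + (J_surface * a / D) * log(R / r)
    },
    sphere = {
      a <- geom$radius; r <- a + x; R <- a + L
      bulk + (J_surface * a^2 / D) * (1 / r - 1 / R)
    })
  if (any(conc <= 0)) {
    stop("scenario error: source flux too strong, concentration field ",
         "reaches zero", call. = FALSE)
  }
  conc
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a self-referencing electrode recording
#'
#' Generates a recording and its ground truth from a
#' [simulation_scenario()]. The ideal electrode voltage at each sample is
#' `intercept + slope * log10(c)` with `c` the steady-state field
#' concentration at the electrode's current distance from the tissue surface
#' (position travel enters through its surface-normal component,
#' `scan_distance * cos(scan_angle)`). The measured voltage follows the
#' first-order lag `dV_m/dt = (V_ideal - V_m)/tau`, starts settled at the
#' initial value, and is summed with `drift * t` and seeded Gaussian noise.
#'
#' @param sc A [simulation_scenario()].
#' @return A list with components `recording` (a `sise_recording`) and
#'   `truth` (data frame, one row per loop: loop index, position index,
#'   loop midpoint time, true flux, true concentrations at the electrode and
#'   at both positions, and the true Nernstian dV = slope * log10(c0/c1)).
#' @export
simulate_recording <- function(sc) {
  stopifnot(inherits(sc, "simulation_scenario"))
  acq <- sc$acquisition
  el <- sc$electrode
  n <- acq$n_samples_per_loop
  N <- n * sc$n_loops
  dt <- acq$sample_interval
  t <- (seq_len(N) - 1L) * dt
  pos_um <- position_waveform(acq, sc$n_loops)

  cosang <- cos(acq$scan_angle * pi / 180)
  dist <- sc$geometry$gap0 + pos_um * 1e-6 * cosang
  J <- flux_at_time(sc$true_flux, t)
  conc <- concentration_field(sc$geometry, sc$ion, sc$bulk_conc, J, dist,
                              L = sc$unstirred_layer)
  v_ideal <- el$intercept + el$slope * log10(conc)

  if (el$tau > 0) {
    a <- exp(-dt / el$tau)
    v_base <- as.numeric(stats::filter((1 - a) * v_ideal, a,
                                       method = "recursive",
                                       init = v_ideal[1]))
  } else {
    v_base <- v_ideal
  }
  v_base <- v_base + el$drift * t / 60
  noise <- function(k) {
    if (el$noise_sd > 0) {
      with_seed(sc$seed + k, stats::rnorm(N, 0, el$noise_sd))
    } else rep(0, N)
  }

  chans <- data.frame(time = t, position_um = pos_um,
                      sise1 = v_base + noise(0L))
  # Channel 2 shares the physical signal but has independent noise; the
  # auxiliary voltage channels carry only the noise floor.
  if (acq$sise2) chans$sise2 <- v_base + noise(1L)
  if (acq$volt1) chans$volt1 <- noise(2L)
  if (acq$volt2) chans$volt2 <- noise(3L)

  meta <- list(
    ion = sc$ion$name, bulk_conc_mM = sc$bulk_conc,
    electrode_slope_mV = el$slope, electrode_intercept_mV = el$intercept,
    tau_s = el$tau, drift_mV_min = el$drift, noise_sd_mV = el$noise_sd,
    seed = sc$seed, n_loops = sc$n_loops,
    unstirred_layer_um = sc$unstirred_layer * 1e6,
    geometry_shape = sc$geometry$shape,
    geometry_gap0_um = sc$geometry$gap0 * 1e6,
    sample_interval_s = acq$sample_interval,
    loop_duration_s = acq$loop_duration,
    scan_distance_um = acq$scan_distance * 1e6,
    scan_angle_deg = acq$scan_angle,
    manipulator_side = acq$manipulator_side,
    start_fit_s = acq$start_fit,
    sise2 = acq$sise2, volt1 = acq$volt1, volt2 = acq$volt2)
  if (!is.null(sc$geometry$radius)) {
    meta$geometry_radius_um <- sc$geometry$radius * 1e6
  }

  # Ground truth per loop, evaluated at the loop midpoint (quasi-static field).
  loop <- seq_len(sc$n_loops)
  t_mid <- (loop - 0.5) * acq$loop_duration
  pos_idx <- as.integer(loop %% 2 == 0)
  J_mid <- flux_at_time(sc$true_flux, t_mid)
  d0 <- sc$geometry$gap0
  d1 <- sc$geometry$gap0 + acq$scan_distance * cosang
  c0 <- concentration_field(sc$geometry, sc$ion, sc$bulk_conc, J_mid, d0,
                            L = sc$unstirred_layer)
  c1 <- concentration_field(sc$geometry, sc$ion, sc$bulk_conc, J_mid, d1,
                            L = sc$unstirred_layer)
  truth <- data.frame(
    loop = loop, position_index = pos_idx, time_mid = t_mid,
    flux_true = J_mid,
    conc_at_electrode_mM = ifelse(pos_idx == 0, c0, c1),
    conc0_mM = c0, conc1_mM = c1,
    dv_true_mV = el$slope * log10(c0 / c1))

  list(recording = recording(chans, meta = meta), truth = truth)
}
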