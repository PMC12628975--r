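# Flux engine: voltage differences -> ion fluxes by two formalisms, with
# geometry and pH-buffer corrections.
#
# Sign convention, used everywhere: J > 0 = net influx into the tissue,
# J < 0 = efflux. Efflux of a cation measured with a non-inverting electrode
# raises the concentration at position 0 above position 1, so
# dV = V0 - V1 > 0; both formulas therefore carry a leading minus sign.
# The ideal-slope factor uses |z| (58/|z| mV/decade) against the *signed*
# calibration slope: for an anion the calibration slope is itself negative,
# which flips the flux sign exactly as Fick's law requires, and an inverting
# amplifier (e.g. -33x) cancels between dV and the calibration slope.

#' Surface-referenced corrected electrode travel distance
#'
#' For curved tissues the steady-state concentration field is not linear in
#' the electrode travel `d = scan_distance * cos(scan_angle)`; replacing `d`
#' by the corrected distance below references the flux to the tissue surface.
#' With tissue radius `a`, `r0 = a + gap0` and `r1 = r0 + d`: flat `dx = d`;
#' cylinder `dx = a ln(r1/r0)`; sphere `dx = a^2 (r1 - r0)/(r0 r1)`. Both
#' curved forms converge to `d` as `a -> Inf`.
#'
#' @param geom A [geometry_spec()].
#' @param scan_distance Electrode travel in metres.
#' @param scan_angle Scan angle above horizontal, degrees.
#' @return Corrected distance `dx` in metres.
#' @examples
#' corrected_distance(geometry_spec("cylinder", radius = 50e-6, gap0 = 50e-6),
#'                    50e-6)  # 50e-6 * ln(1.5) = 20.27 um
#' @export
corrected_distance <- function(geom, scan_distance, scan_angle = 0) {
  stopifnot(inherits(geom, "geometry_spec"))
  d <- scan_distance * cos(scan_angle * pi / 180)
  stopifnot(d > 0)
  switch(geom$shape,
    flat = d,
    cylinder = {
      r0 <- geom$radius + geom$gap0
      geom$radius * log((r0 + d) / r0)
    },
    sphere = {
      r0 <- geom$radius + geom$gap0
      geom$radius^2 * d / (r0 * (r0 + d))
    })
}

#' Flux analysis configuration
#'
#' Bundles the method choice, ion, bath concentration, geometry and optional
#' pH-buffer correction for [analyse_recording()] and the single-estimate
#' flux functions.
#'
#' @param method `"chemical_potential"` (flux from dV, bath concentration and
#'   ionic mobility) or `"diffusion_gradient"` (Fick's law on the
#'   back-calculated concentrations at both positions).
#' @param ion Ion name or `ion_species`.
#' @param bath_conc Average bath concentration in mM; required for the
#'   chemical-potential method unless `use_position1_conc` is set.
#' @param use_position1_conc Replace the bath concentration by the measured
#'   concentration at position 1 in the chemical-potential formula; corrects
#'   the underestimate that occurs when strong fluxes raise the local
#'   concentration well above the bulk value.
#' @param geometry A [geometry_spec()].
#' @param scan_distance,scan_angle Electrode travel (m) and angle (degrees).
#' @param buffer Optional pH-buffer correction (H+ analyses only): a list
#'   with `name` (buffer name), `conc_mM` (total buffer concentration) and
#'   `pH` (nominal solution pH, used to validate polyprotic buffers and in
#'   the chemical-potential correction ratio).
#' @return An object of class `flux_config` with the resolved ion, buffer and
#'   precomputed corrected distance `dx`.
#' @export
flux_config <- function(method = c("chemical_potential", "diffusion_gradient"),
                        ion = "K+", bath_conc = NULL,
                        use_position1_conc = FALSE,
                        geometry = geometry_spec("flat"),
                        scan_distance = 50e-6, scan_angle = 0,
                        buffer = NULL) {
  method <- match.arg(method)
  ion <- ion_species(ion)
  if (method == "chemical_potential" && !use_position1_conc) {
    if (is.null(bath_conc) || bath_conc <= 0) {
      stop("chemical_potential method requires a positive bath_conc (mM)",
           call. = FALSE)
    }
  }
  buf <- NULL
  if (!is.null(buffer)) {
    if (ion$name != "H+") {
      stop("buffer correction applies only to H+ analyses (got ion '",
           ion$name, "')", call. = FALSE)
    }
    stopifnot(is.list(buffer), !is.null(buffer$name),
              !is.null(buffer$conc_mM), buffer$conc_mM > 0,
              !is.null(buffer$pH))
    buf <- list(species = buffer_species(buffer$name,
                                         solution_pH = buffer$pH),
                conc_mM = buffer$conc_mM, pH = buffer$pH)
  }
  structure(list(method = method, ion = ion, bath_conc = bath_conc,
                 use_position1_conc = isTRUE(use_position1_conc),
                 geometry = geometry, scan_distance = scan_distance,
                 scan_angle = scan_angle,
                 dx = corrected_distance(geometry, scan_distance, scan_angle),
                 buffer = buf),
            class = "flux_config")
}

#' Flux by the chemical-potential method
#'
#' `J = -C_eff * u * ((58/|z|) / slope_cal) * (dV / dx)` with `dV` in volts,
#' `dx` the corrected distance in metres and `C_eff` the bath concentration
#' (or the measured position-1 concentration when `use_position1_conc` is
#' set) in mol m^-3. Only the *slope* of the calibration enters, which makes
#' this method insensitive to electrode drift.
#'
#' @param dv A `dv_estimate` from [dv_triple()].
#' @param cfg A [flux_config()].
#' @param cal A `sise_calibration` (needed for the slope, and for the
#'   position-1 concentration when `use_position1_conc` is set).
#' @return Flux in mol m^-2 s^-1; negative = efflux.
#' @export
flux_chemical_potential <- function(dv, cfg, cal) {
  stopifnot(inherits(dv, "dv_estimate"), inherits(cfg, "flux_config"),
            inherits(cal, "sise_calibration"))
  if (cal$slope == 0) stop("calibration slope is zero", call. = FALSE)
  C_eff <- if (cfg$use_position1_conc) {
    voltage_to_concentration(cal, dv$V1)
  } else {
    cfg$bath_conc
  }
  -C_eff * cfg$ion$u *
    ((NERNST_SLOPE_IDEAL_MV / abs(cfg$ion$z)) / cal$slope) *
    (dv$dv * 1e-3) / cfg$dx
}

#' Flux by the diffusion-gradient (Fick) method
#'
#' Back-calculates the concentrations at positions 0 and 1 from the fitted
#' voltages and applies Fick's law over the corrected distance:
#' `J = -D (c0 - c1) / dx`.
#'
#' @inheritParams flux_chemical_potential
#' @return Flux in mol m^-2 s^-1; negative = efflux.
#' @export
flux_diffusion_gradient <- function(dv, cfg, cal) {
  stopifnot(inherits(dv, "dv_estimate"), inherits(cfg, "flux_config"),
            inherits(cal, "sise_calibration"))
  c0 <- voltage_to_concentration(cal, dv$V0)  # mM = mol m^-3
  c1 <- voltage_to_concentration(cal, dv$V1)
  D <- diffusion_coefficient(cfg$ion)
  -D * (c0 - c1) / cfg$dx
}

#' Buffer flux ratio for the chemical-potential correction
#'
#' Ratio between the flux carried as protonated buffer and the flux of free
#' H+, computed as
#' `(u_HA / u_H+) * C * 1e-3 * 10^pK * (10^pH / (10^pK + 10^pH))^2`,
#' with `C` the total buffer concentration in mM (the `1e-3` factor converts
#' to molar).
#'
#' @param buf A `buffer_species` or buffer name.
#' @param C_buf_mM Total buffer concentration (protonated plus dissociated
#'   form) in mM.
#' @param pH Solution pH.
#' @return Dimensionless nonnegative ratio.
#' @export
buffer_ratio <- function(buf, C_buf_mM, pH) {
  buf <- buffer_species(buf, solution_pH = pH)
  stopifnot(C_buf_mM >= 0)
  u_H <- ion_species("H+")$u
  (buf$u_HA / u_H) * C_buf_mM * 1e-3 * 10^buf$pK *
    (10^pH / (10^buf$pK + 10^pH))^2
}

#' Total proton flux from the buffer ratio
#'
#' `J_total = (r + 1) * J_H`.
#'
#' @param J_H Free-H+ flux, mol m^-2 s^-1.
#' @param r Buffer ratio from [buffer_ratio()].
#' @return Total flux, mol m^-2 s^-1.
#' @export
correct_flux_chemical <- function(J_H, r) {
  stopifnot(r >= 0)
  (r + 1) * J_H
}

#' Protonated buffer concentration
#'
#' `[HA] = C * 10^pK / (10^pH + 10^pK)`: the fraction of the total buffer in
#' the protonated form at a given pH.
#'
#' @inheritParams buffer_ratio
#' @return `[HA]` in the same units as `C_buf_mM`.
#' @export
protonated_concentration <- function(buf, C_buf_mM, pH) {
  buf <- buffer_species(buf, solution_pH = pH)
  stopifnot(C_buf_mM > 0)
  C_buf_mM / (10^(pH - buf$pK) + 1)
}

#' Total proton flux via Fick transport of the protonated buffer
#'
#' Computes the protonated-buffer concentrations at both positions from the
#' measured pH values, the buffer flux `J_HA = -D_HA ([HA]_0 - [HA]_1) / dx`
#' (same sign convention as the ion flux), and returns
#' `J_total = J_H + J_HA`.
#'
#' @param J_H Free-H+ flux, mol m^-2 s^-1.
#' @param buf A `buffer_species` or buffer name.
#' @param C_buf_mM Total buffer concentration in mM.
#' @param pH0,pH1 pH at positions 0 and 1 (from the H+ channel
#'   concentrations).
#' @param dx Corrected distance in metres.
#' @return Total flux, mol m^-2 s^-1.
#' @export
correct_flux_fick <- function(J_H, buf, C_buf_mM, pH0, pH1, dx) {
  if (is.null(pH0) || is.null(pH1) || !is.finite(pH0) || !is.finite(pH1)) {
    stop("Fick buffer correction requires pH at both positions", call. = FALSE)
  }
  buf <- buffer_species(buf, solution_pH = (pH0 + pH1) / 2)
  HA0 <- protonated_concentration(buf, C_buf_mM, pH0)  # mM = mol m^-3
  HA1 <- protonated_concentration(buf, C_buf_mM, pH1)
  J_H + (-buf$D_HA * (HA0 - HA1) / dx)
}
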