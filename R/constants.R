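# Physical constants shared by the calibration, simulator and flux modules.
# The ideal Nernstian slope is fixed at 58 mV per decade (not 59.2): the
# original instrument uses 58 and temperature is not a parameter anywhere in
# the pipeline, so every module must agree on the same constant.

#' Ideal Nernstian electrode slope
#'
#' The theoretical response of a perfectly ion-selective electrode is
#' `58/z` mV per tenfold change in concentration, where `z` is the signed
#' valency of the ion. The constant 58 mV is fixed (it is not
#' temperature-adjustable); electrode quality is judged by comparing the
#' fitted calibration slope against this value.
#'
#' @param z Signed integer valency (e.g. `+1` for K+, `-1` for Cl-).
#' @return Ideal slope in mV per decade (signed).
#' @examples
#' ideal_slope(1)   # 58
#' ideal_slope(-1)  # -58
#' ideal_slope(2)   # 29
#' @export
ideal_slope <- function(z) {
  stopifnot(is.numeric(z), z != 0)
  NERNST_SLOPE_IDEAL_MV / z
}

# 58 mV per decade, the slope of an ideally selective monovalent electrode.
NERNST_SLOPE_IDEAL_MV <- 58

# Thermal ("Einstein") voltage implied by the 58 mV slope: S/ln(10) in volts.
# Links mobility to diffusivity as D = u * EINSTEIN_VOLTAGE_V / |z|, so the
# chemical-potential and diffusion-gradient flux formalisms coincide exactly
# in the small-gradient limit.
EINSTEIN_VOLTAGE_V <- (NERNST_SLOPE_IDEAL_MV / 1000) / log(10)
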