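# Nernstian electrode calibration: voltage is linear in log10(concentration).

#' Fit an electrode calibration curve
#'
#' Ordinary least squares of electrode voltage (mV) against
#' log10(concentration / 1 mM). The fitted slope (mV per decade) and intercept
#' (mV at 1 mM) define the voltage-to-concentration conversion. The slope is
#' signed: anion electrodes, or setups with an inverting amplifier, give
#' negative slopes, and all downstream flux formulas use the signed value.
#'
#' @param conc_mM Concentrations of the calibration solutions in mM (all > 0),
#'   or a two-column data frame `(conc_mM, voltage_mV)`.
#' @param voltage_mV Corresponding electrode voltages in mV.
#' @return An object of class `sise_calibration`: list with `slope`
#'   (mV/decade), `intercept` (mV at 1 mM), `r_squared`, `n` and the input
#'   `points`.
#' @examples
#' fit_calibration(c(0.1, 1, 10), c(-58, 0, 58))
#' @export
fit_calibration <- function(conc_mM, voltage_mV = NULL) {
  if (is.data.frame(conc_mM)) {
    stopifnot(ncol(conc_mM) >= 2)
    voltage_mV <- conc_mM[[2]]
    conc_mM <- conc_mM[[1]]
  }
  stopifnot(length(conc_mM) == length(voltage_mV))
  if (any(!is.finite(conc_mM)) || any(conc_mM <= 0)) {
    stop("calibration concentrations must all be positive", call. = FALSE)
  }
  if (length(unique(conc_mM)) < 2) {
    stop("calibration needs at least 2 distinct concentrations", call. = FALSE)
  }
  logc <- log10(conc_mM)
  fit <- stats::lm(voltage_mV ~ logc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || abs(slope) < 1) {
    stop("degenerate electrode: |calibration slope| below 1 mV/decade",
         call. = FALSE)
  }
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((voltage_mV - mean(voltage_mV))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = length(conc_mM),
                 points = data.frame(conc_mM = conc_mM,
                                     voltage_mV = voltage_mV)),
            class = "sise_calibration")
}

#' @export
print.sise_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration>  slope = %.4g mV/decade, intercept = %.4g mV at 1 mM, r^2 = %.6f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert an electrode voltage to a concentration
#'
#' Inverts the fitted calibration line: `c = 10^((V - intercept)/slope)` mM.
#'
#' @param cal A `sise_calibration` object.
#' @param voltage_mV Electrode voltage(s) in mV.
#' @return Concentration(s) in mM (numerically equal to mol m^-3).
#' @export
voltage_to_concentration <- function(cal, voltage_mV) {
  stopifnot(inherits(cal, "sise_calibration"))
  10^((voltage_mV - cal$intercept) / cal$slope)
}

#' Convert a concentration to the ideal electrode voltage
#'
#' The forward calibration line, `V = intercept + slope * log10(c / 1 mM)`.
#'
#' @inheritParams voltage_to_concentration
#' @param conc_mM Concentration(s) in mM, all > 0.
#' @return Voltage(s) in mV.
#' @export
concentration_to_voltage <- function(cal, conc_mM) {
  stopifnot(inherits(cal, "sise_calibration"), all(conc_mM > 0))
  cal$intercept + cal$slope * log10(conc_mM)
}

#' Read a calibration table from a file
#'
#' Tab-separated file with two columns, `conc_mM` and `voltage_mV`; lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @return A data frame suitable for [fit_calibration()].
#' @export
read_calibration_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("conc_mM", "voltage_mV") %in% names(tab))) {
    stop("calibration table must have columns 'conc_mM' and 'voltage_mV'",
         call. = FALSE)
  }
  tab[, c("conc_mM", "voltage_mV")]
}
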