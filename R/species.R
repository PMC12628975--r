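# Ion and buffer species tables. Shipped as editable tab-separated files in
# inst/extdata so users can override mobilities without touching code.

.species_env <- new.env(parent = emptyenv())

species_file <- function(which) {
  system.file("extdata", which, package = "iseflux", mustWork = TRUE)
}

load_species_table <- function(which) {
  key <- which
  if (is.null(.species_env[[key]])) {
    tab <- utils::read.delim(species_file(which), comment.char = "#",
                             stringsAsFactors = FALSE)
    .species_env[[key]] <- tab
  }
  .species_env[[key]]
}

#' List the ions shipped with the package
#'
#' @return A data frame with columns `name`, `z` (signed valency) and `u`
#'   (ionic mobility, m^2 V^-1 s^-1).
#' @export
list_ions <- function() load_species_table("ion_mobilities.tsv")

#' List the pH buffers shipped with the package
#'
#' @return A data frame with columns `name`, `pK`, `u_HA`, `D_HA` and
#'   `polyprotic`.
#' @export
list_buffers <- function() load_species_table("buffer_table.tsv")

#' Look up an ion species
#'
#' Returns the signed valency and ionic mobility of an ion from the shipped
#' table of limiting ionic mobilities (see
#' `system.file("extdata", "ion_mobilities.tsv", package = "iseflux")` for the
#' values and their source).
#'
#' @param name Ion name, e.g. `"K+"`, `"H+"`, `"Ca2+"`, `"Cl-"`.
#' @return An object of class `ion_species`: a list with `name`, `z`
#'   (signed integer valency) and `u` (mobility, m^2 V^-1 s^-1).
#' @examples
#' ion_species("K+")
#' @export
ion_species <- function(name) {
  if (inherits(name, "ion_species")) return(name)
  tab <- list_ions()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown ion species '", name, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  sp <- list(name = tab$name[i], z = as.integer(tab$z[i]), u = tab$u[i])
  stopifnot(sp$z != 0, sp$u > 0)
  structure(sp, class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion %s>  z = %+d,  u = %.3g m^2 V^-1 s^-1,  D = %.3g m^2 s^-1\n",
              x$name, x$z, x$u, diffusion_coefficient(x)))
  invisible(x)
}

#' Diffusion coefficient of an ion
#'
#' Derived from the ionic mobility by the Einstein relation
#' `D = u * (S / ln 10) / |z|` with `S = 0.058` V, the same voltage scale as
#' the ideal electrode slope. Using this single constant everywhere makes the
#' chemical-potential and diffusion-gradient flux estimates agree exactly in
#' the small-gradient limit.
#'
#' @param species An `ion_species` object or an ion name.
#' @return Diffusion coefficient in m^2 s^-1.
#' @examples
#' diffusion_coefficient("K+")  # about 1.92e-9
#' @export
diffusion_coefficient <- function(species) {
  sp <- ion_species(species)
  sp$u * EINSTEIN_VOLTAGE_V / abs(sp$z)
}

#' Look up a pH buffer
#'
#' Returns the dissociation exponent and protonated-form transport constants
#' of a buffer from the shipped table. Organic-acid buffers with several
#' pK_A values (flagged `polyprotic`) are only valid when the solution pH is
#' within 0.25 pH units of the single tabulated pK; outside that window the
#' single-pK correction formulas do not apply and the lookup refuses.
#'
#' @param name Buffer name, e.g. `"Mes"`, `"TRIS"`, `"citrate"`.
#' @param solution_pH pH of the bath solution; required to validate
#'   polyprotic buffers.
#' @return An object of class `buffer_species`: list with `name`, `pK`,
#'   `u_HA` (mobility of the protonated form, m^2 V^-1 s^-1), `D_HA`
#'   (diffusion coefficient of the protonated form, m^2 s^-1) and
#'   `polyprotic` flag.
#' @examples
#' buffer_species("Mes", solution_pH = 6.1)
#' @export
buffer_species <- function(name, solution_pH = NULL) {
  if (inherits(name, "buffer_species")) return(name)
  tab <- list_buffers()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown buffer '", name, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  buf <- list(name = tab$name[i], pK = tab$pK[i], u_HA = tab$u_HA[i],
              D_HA = tab$D_HA[i], polyprotic = as.logical(tab$polyprotic[i]))
  stopifnot(buf$u_HA > 0, buf$D_HA > 0, buf$pK > 0, buf$pK < 14)
  if (buf$polyprotic) {
    if (is.null(solution_pH)) {
      stop("buffer '", buf$name, "' is polyprotic: solution_pH is required ",
           "to check that |pH - pK| <= 0.25", call. = FALSE)
    }
    if (abs(solution_pH - buf$pK) > 0.25) {
      stop("buffer '", buf$name, "' has several pK_A values and can only be ",
           "used when the solution pH is within 0.25 units of pK = ", buf$pK,
           " (got pH ", solution_pH, ")", call. = FALSE)
    }
  }
  structure(buf, class = "buffer_species")
}

#' @export
print.buffer_species <- function(x, ...) {
  cat(sprintf("<buffer %s>  pK = %.2f,  u_HA = %.3g,  D_HA = %.3g%s\n",
              x$name, x$pK, x$u_HA, x$D_HA,
              if (x$polyprotic) "  [polyprotic]" else ""))
  invisible(x)
}
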