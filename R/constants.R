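#' Physical constants used throughout the package
#'
#' Units are fixed package-wide: energies in kcal/mol, lengths in Angstrom,
#' temperature in Kelvin, masses in internal units (all 1 by default), time in
#' internal units. Only equilibrium averages matter for the thermodynamics, so
#' the absolute time scale is irrelevant.
#'
#' @format `KB` is the Boltzmann (gas) constant in kcal mol^-1 K^-1.
#' @name constants
NULL

#' @rdname constants
#' @export
KB <- 1.9872041e-3

# kB*T/h prefactor for the Eyring equation, s^-1 per Kelvin.
# From CODATA k_B = 1.380649e-23 J/K and h = 6.62607015e-34 J*s:
# k_B/h = 2.0836619e10 s^-1 K^-1, giving 6.25e12 s^-1 at 300 K.
KB_OVER_H <- 1.380649e-23 / 6.62607015e-34

.assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric, got: ",
         paste(utils::head(x, 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
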