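#' Gas constant in kcal/(mol K)
#'
#' Value used throughout for Gibbs energies and van't Hoff relations.
#' @export
R_KCAL <- 1.9872e-3

#' Convert degrees Celsius to kelvin
#'
#' All thermodynamic computations run in kelvin; instrument tables use
#' Celsius. The offset is 273.15 exactly.
#' @param x temperature in degrees C
#' @return temperature in K
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert kelvin to degrees Celsius
#' @param x temperature in K
#' @return temperature in degrees C
#' @export
kelvin_to_celsius <- function(x) x - 273.15
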