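#' @keywords internal
"_PACKAGE"

# Gas constant in kcal mol^-1 K^-1; fixed so that free-energy differences
# are reported in the same units as the selectivity literature.
R_KCAL <- 1.98720425e-3

# Largest enantiomeric excess accepted by the conversion: beyond this the
# free-energy difference is numerically meaningless (ee = 1 diverges).
EE_MAX <- 0.999

#' Convert enantiomeric excess to a free-energy difference
#'
#' Under Curtin–Hammett kinetic control the enantiomer ratio reflects the
#' free-energy gap between the competing enantiodetermining transition
#' states: \eqn{\Delta\Delta G = R T \ln\{(1 + ee)/(1 - ee)\}}. This is the
#' regression target used throughout the package, in kcal/mol.
#'
#' @param ee Enantiomeric excess as a fraction in `[0, 0.999]` (unsigned;
#'   a consistent major enantiomer is assumed across a dataset). Values
#'   above 0.999 are rejected rather than clamped so that saturated
#'   measurements cannot silently produce divergent targets.
#' @param temperature Absolute temperature in Kelvin (> 0).
#' @return Free-energy difference in kcal/mol, same length as `ee`.
#' @seealso [ddg_to_ee()] for the inverse.
#' @examples
#' ee_to_ddg(0.92, 298.15) # ~1.883 kcal/mol
#' @export
ee_to_ddg <- function(ee, temperature) {
  stopifnot(is.numeric(ee), is.numeric(temperature))
  if (any(!is.finite(ee)) || any(ee < 0) || any(ee > EE_MAX)) {
    stop("'ee' must be a fraction in [0, ", EE_MAX,
         "]; ee = 1 corresponds to a divergent free-energy difference",
         call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("'temperature' must be positive (Kelvin)", call. = FALSE)
  }
  R_KCAL * temperature * log((1 + ee) / (1 - ee))
}

#' Convert a free-energy difference to enantiomeric excess
#'
#' Inverse of [ee_to_ddg()]: \eqn{ee = \tanh\{\Delta\Delta G / (2 R T)\}}.
#' Total over the real line; the sign of the output follows the sign of
#' `ddg` and the reported e.e. is its absolute value.
#'
#' @param ddg Free-energy difference in kcal/mol.
#' @param temperature Absolute temperature in Kelvin (> 0).
#' @return Signed enantiomeric excess in `(-1, 1)`.
#' @examples
#' ddg_to_ee(1.883, 298.15) # ~0.92
#' @export
ddg_to_ee <- function(ddg, temperature) {
  stopifnot(is.numeric(ddg), is.numeric(temperature))
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("'temperature' must be positive (Kelvin)", call. = FALSE)
  }
  tanh(ddg / (2 * R_KCAL * temperature))
}

#' Convert degrees Celsius to Kelvin
#'
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @examples
#' celsius_to_kelvin(25) # 298.15
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
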