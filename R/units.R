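#' Unit conversion helpers
#'
#' The package works in SI units internally (m, Pa, Pa.s, m^3/s). These
#' helpers convert the bench-side units used around a fluidic plate:
#' mL/min for pump flow rates, mm/um for channel dimensions, mPa.s for
#' viscosity and dyn/cm^2 for wall shear stress (1 dyn/cm^2 = 0.1 Pa).
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ml_min_to_m3_s <- function(x) x * 1e-6 / 60

#' @rdname units
#' @export
m3_s_to_ml_min <- function(x) x * 60 * 1e6

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
mpas_to_pas <- function(x) x * 1e-3

#' @rdname units
#' @export
pa_to_dyn_cm2 <- function(x) x * 10

#' @rdname units
#' @export
dyn_cm2_to_pa <- function(x) x / 10

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
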