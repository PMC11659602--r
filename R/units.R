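#' Unit conversions
#'
#' Centralised conversions between the interface units (micromolar
#' concentrations, per-minute rates) and SI units (molar, per-second).
#' All second-order efficiency constants are reported in M^-1 min^-1 to
#' match the convention of covalent-kinetics tables.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
uM_to_M <- function(x) x * 1e-6

#' @rdname units
#' @export
M_to_uM <- function(x) x * 1e6

#' @rdname units
#' @export
per_min_to_per_s <- function(x) x / 60

#' @rdname units
#' @export
per_s_to_per_min <- function(x) x * 60
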