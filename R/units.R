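#' Unit conversion helpers
#'
#' The internal unit system is centimetres, seconds and mol/cm^3.
#' Configuration files may declare lengths in micrometres and
#' concentrations in picomolar; these helpers convert at the boundary.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
#' @keywords internal
NULL

#' @rdname units
um_to_cm <- function(x) x * 1e-4

#' @rdname units
cm_to_um <- function(x) x * 1e4

#' Convert picomolar to mol/cm^3 (and back)
#'
#' 1 pM = 1e-12 mol/L = 1e-15 mol/cm^3.
#'
#' @param x numeric vector.
#' @return numeric vector.
#' @export
pM_to_mol_cm3 <- function(x) x * 1e-15

#' @rdname pM_to_mol_cm3
#' @export
mol_cm3_to_pM <- function(x) x * 1e15

#' Avogadro constant (molecules per mole)
#' @keywords internal
AVOGADRO <- 6.022140857e23

.time_unit_seconds <- c(s = 1, min = 60, h = 3600, d = 86400, day = 86400)

#' Convert a half-life to a first-order clearance rate
#'
#' Uses the standard relation \eqn{k = \ln 2 / t_{1/2}}.  A 72 h
#' serum half-life of VEGF Trap corresponds to a clearance rate of
#' 1.6e-4 per minute.
#'
#' @param half_life positive numeric, the half-life.
#' @param unit time unit of `half_life`: one of `"s"`, `"min"`, `"h"`, `"d"`.
#' @param out_unit time unit of the returned rate (rate is per `out_unit`).
#' @return first-order rate constant (per `out_unit`).
#' @examples
#' half_life_to_clearance(72, "h", "min")  # 1.6e-4 min^-1
#' @export
half_life_to_clearance <- function(half_life, unit = "h", out_unit = "min") {
  stopifnot(is.numeric(half_life), half_life > 0)
  unit <- match.arg(unit, names(.time_unit_seconds))
  out_unit <- match.arg(out_unit, names(.time_unit_seconds))
  t_sec <- half_life * .time_unit_seconds[[unit]]
  log(2) / t_sec * .time_unit_seconds[[out_unit]]
}

#' Convert a time quantity between units
#' @param x numeric vector.
#' @param from,to units among `"s"`, `"min"`, `"h"`, `"d"`.
#' @return numeric vector in unit `to`.
#' @export
convert_time <- function(x, from = "d", to = "s") {
  from <- match.arg(from, names(.time_unit_seconds))
  to <- match.arg(to, names(.time_unit_seconds))
  x * .time_unit_seconds[[from]] / .time_unit_seconds[[to]]
}
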