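# Closed-form worst-case bounds on the overlay misalignment caused by the
# display rounding of the live geometry values (table/SID/FD in whole cm,
# angles in whole degrees). Both bounds are evaluated at the largest
# projection magnification, i.e. at maximal SID, and measure the maximal
# possible deviation along the optical axis between two images sharing the
# same displayed configuration.

check_bound_query <- function(spd, sid_max) {
  stopifnot(is.numeric(spd), is.numeric(sid_max))
  if (!(spd > 0)) stop("spd must be positive")
  if (!(sid_max >= spd)) stop("sid_max must be at least spd")
}

#' Table-rounding displacement bound
#'
#' Worst-case overlay displacement on the detector caused by rounding the
#' displayed table coordinate to whole centimetres: the 1 cm rounding span
#' magnified from iso-center to detector,
#' `eps_t = table_rounding / SPD * SID_max`.
#'
#' @param spd Source-to-patient distance, mm.
#' @param sid_max Maximal source-image distance, mm.
#' @param table_rounding Rounding span of the displayed table coordinate, mm
#'   (default 10 mm = 1 cm display precision).
#' @return Displacement bound in mm.
#' @examples
#' eps_table(spd = 810, sid_max = 1200)  # frontal C-arm: 14.8 mm
#' eps_table(spd = 765, sid_max = 1300)  # lateral C-arm: 16.99 mm
#' @export
eps_table <- function(spd, sid_max, table_rounding = 10) {
  check_bound_query(spd, sid_max)
  stopifnot(table_rounding > 0)
  table_rounding / spd * sid_max
}

#' Angulation-rounding displacement bound
#'
#' Worst-case displacement caused by rounding the displayed angulation to
#' whole degrees, from the law of cosines on the triangle spanned at the
#' detector by two rays one rounding step apart:
#' `eps_a = sqrt(b^2 + L^2 - 2 b L cos(theta))` with `L = SID_max - SPD` and
#' `b = sin(90 deg) * L / sin(90 deg - theta)`.
#'
#' @inheritParams eps_table
#' @param angle_rounding Rounding span of the displayed angulation, degrees
#'   (default 1).
#' @return Displacement bound in mm.
#' @examples
#' eps_angulation(spd = 810, sid_max = 1200)  # frontal C-arm: 6.8 mm
#' @export
eps_angulation <- function(spd, sid_max, angle_rounding = 1) {
  check_bound_query(spd, sid_max)
  stopifnot(angle_rounding >= 0, angle_rounding < 90)
  th <- deg2rad(angle_rounding)
  L <- sid_max - spd
  b <- sin(pi / 2) * L / sin(pi / 2 - th)
  sqrt(b^2 + L^2 - 2 * b * L * cos(th))
}

#' Both rounding-error bounds at once
#'
#' @inheritParams eps_table
#' @inheritParams eps_angulation
#' @return Named list `eps_table_mm`, `eps_angulation_mm`.
#' @export
rounding_error_bounds <- function(spd, sid_max, table_rounding = 10,
                                  angle_rounding = 1) {
  list(eps_table_mm = eps_table(spd, sid_max, table_rounding),
       eps_angulation_mm = eps_angulation(spd, sid_max, angle_rounding))
}
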