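# Time-dependent tissue program schedules. The stepper applies these same
# rules internally; the exported forms document and expose them.

#' Anterior-end position under PSM shortening
#'
#' The anterior end of the PSM moves posteriorly at constant speed:
#' `xa(t) = ua t`, so the PSM length is `L(t) = Lx - ua t`.
#'
#' @param t time(s), min.
#' @param ua anterior-end speed, um/min.
#' @return anterior-end position(s), um.
#' @seealso [program_params()]; the segment-length constraint `va + ua = c`.
#' @export
anterior_position <- function(t, ua) {
  stopifnot(all(t >= 0), ua >= 0)
  ua * t
}

#' Tube radius schedule under radial shrinkage
#'
#' `r(t) = r0 - sr t`, floored at `min(2 dc, r0)` to keep the geometry
#' non-degenerate. After each radius update the simulation repositions cells
#' left outside the wall to `rho = r(t) - 2 rb`.
#'
#' @param t time(s), min.
#' @param sr shrink rate, um/min.
#' @param r0 initial tube radius, um.
#' @param dc cell diameter, um (sets the floor).
#' @return radius value(s), um.
#' @export
radius_schedule <- function(t, sr, r0, dc = 11) {
  stopifnot(all(t >= 0), sr >= 0, r0 > 0)
  pmax(r0 - sr * t, min(2 * dc, r0))
}
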