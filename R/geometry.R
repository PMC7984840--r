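# Geometry operations: region membership, local coordinates, confinement.

.as_pos_matrix <- function(position) {
  if (is.null(dim(position))) {
    stopifnot(length(position) == 3L)
    position <- matrix(as.numeric(position), nrow = 1L)
  }
  storage.mode(position) <- "double"
  position
}

#' Classify positions into tissue regions
#'
#' Points with `x < xa` lie in the formed-segment (anterior) region, points
#' with `x >= Xc` in the tailbud half-toroid; the rest belong to the left or
#' right PSM tube according to which tube axis is nearer in y.
#'
#' @param position numeric 3-vector or n x 3 matrix of positions (um).
#' @param geom a [geometry_params()] object.
#' @param xa anterior-end position, um.
#' @return character vector of tags: `"anterior"`, `"left_psm"`,
#'   `"right_psm"`, `"tailbud"`.
#' @export
classify_domain <- function(position, geom, xa = 0) {
  position <- .as_pos_matrix(position)
  tags <- c("anterior", "left_psm", "right_psm", "tailbud")
  tags[cpp_classify_domain(position, unclass(geom), xa) + 1L]
}

#' Tube-local cylindrical coordinates
#'
#' Radial distance `rho` from the side's tube axis and tube angle `q`
#' (measured from +y, counterclockwise in the y-z plane; `q = 0` by
#' convention on the axis). The axial coordinate is unchanged.
#'
#' @inheritParams classify_domain
#' @param side `"left"` or `"right"`.
#' @return data.frame with columns `x`, `rho`, `q`.
#' @seealso [tube_position()] for the inverse transform.
#' @export
tube_coords <- function(position, geom, side = c("left", "right")) {
  side <- match.arg(side)
  m <- cpp_tube_coords(.as_pos_matrix(position), unclass(geom),
                       if (side == "left") 1L else 2L)
  data.frame(x = m[, 1], rho = m[, 2], q = m[, 3])
}

#' Inverse of [tube_coords()]
#'
#' @param x,rho,q axial position (um), radial distance (um) and tube angle
#'   (rad).
#' @inheritParams tube_coords
#' @return n x 3 position matrix.
#' @export
tube_position <- function(x, rho, q, geom, side = c("left", "right")) {
  side <- match.arg(side)
  cpp_tube_position(cbind(x, rho, q), unclass(geom),
                    if (side == "left") 1L else 2L)
}

#' Tailbud-local toroidal coordinates
#'
#' `p` is the azimuth in the torus mid-plane measured from the left-tube
#' junction (`p = 0` joins the left tube, `p = pi` the right tube), `rho` the
#' distance from the torus core circle and `q` the poloidal angle.
#'
#' @inheritParams classify_domain
#' @return data.frame with columns `p`, `rho`, `q`.
#' @export
torus_coords <- function(position, geom) {
  m <- cpp_torus_coords(.as_pos_matrix(position), unclass(geom))
  data.frame(p = m[, 1], rho = m[, 2], q = m[, 3])
}

#' Inverse of [torus_coords()]
#'
#' @param p,rho,q toroidal coordinates as returned by [torus_coords()].
#' @inheritParams classify_domain
#' @return n x 3 position matrix.
#' @export
torus_position <- function(p, rho, q, geom) {
  cpp_torus_position(cbind(p, rho, q), unclass(geom))
}

#' Confinement force of the tissue boundary
#'
#' Frictionless wall force pointing along the inward wall normal with
#' magnitude `mub * exp(-(r - rho)/rb)` where `rho` is the local radial
#' coordinate (tube or torus); in the tubes the force has no x-component.
#' During initialization an additional wall at `x = xa` can be enabled.
#'
#' @inheritParams classify_domain
#' @param r current tube radius, um (defaults to `geom$r0`).
#' @param mub,rb force coefficient (um/min) and decay length (um).
#' @param anterior_wall add the relaxation wall at `x = xa`?
#' @return n x 3 matrix of forces (um/min).
#' @export
boundary_force <- function(position, geom, xa = 0, r = geom$r0,
                           mub = 20, rb = 1, anterior_wall = FALSE) {
  cpp_boundary_force_mat(.as_pos_matrix(position), unclass(geom), xa, r,
                         isTRUE(anterior_wall), mub, rb)
}
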