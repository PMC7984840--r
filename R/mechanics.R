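# Cell mechanics: advection field, motility gradient, polarity random walk,
# pairwise repulsion and assembly of the net overdamped velocity.

#' Advection velocity field
#'
#' In the tailbud reference frame cells are advected toward the anterior
#' (negative x) with a piecewise-linear speed profile in the scaled
#' coordinate `chi = (x - xa)/L`: speed `va` at the anterior end (`chi` = 0),
#' `vp (1 - chi)` posterior to the knot `xq`, and zero at the posterior tip.
#' Before the switching time `tg` the posterior parameter is `vp_early`,
#' after it `vp_late`.
#'
#' @param x axial position(s), um.
#' @param xa anterior-end position, um.
#' @param L current PSM length, um.
#' @param params a [mechanics_params()] object.
#' @param t simulation time, min (selects `vp_early` vs `vp_late`).
#' @return n x 3 matrix of velocities `(-v(chi), 0, 0)` in um/min.
#' @export
advection_velocity <- function(x, xa, L, params, t = 0) {
  chi <- (x - xa) / L
  vp <- if (t < params$tg) params$vp_early else params$vp_late
  v <- cpp_advection_speed(as.numeric(chi), params$va, vp, params$xq)
  cbind(-v, 0, 0)
}

#' Local strain rate of the advection field
#'
#' The magnitude of the spatial gradient of advection speed: `vp / L` in the
#' posterior subdomain and `|va - vp (1 - xq)| / (xq L)` in the anterior one.
#'
#' @param chi scaled axial coordinate(s) in \[0, 1\].
#' @param L current PSM length, um.
#' @inheritParams advection_velocity
#' @return strain rate(s), 1/min.
#' @export
strain_rate <- function(chi, L, params, t = 0) {
  vp <- if (t < params$tg) params$vp_early else params$vp_late
  ifelse(chi > params$xq,
         vp / L,
         abs(params$va - vp * (1 - params$xq)) / (params$xq * L))
}

#' Intrinsic cell motility gradient
#'
#' `v0 = vs / (1 + ((1 - chi)/Xv)^h)` with `chi = (x - xa)/L`: highest at the
#' posterior tip (`v0 = vs`), decaying toward the anterior.
#'
#' @inheritParams advection_velocity
#' @return speed(s), um/min.
#' @export
motility_speed <- function(x, xa, L, params) {
  chi <- (x - xa) / L
  cpp_motility_speed(as.numeric(chi), params$vs, params$Xv, params$h)
}

#' One Euler-Maruyama step of the polarity random walk
#'
#' The polarity unit vector performs an isotropic random walk on the unit
#' sphere: an increment `sqrt(2 Dphi dt) (xi1 mx + xi2 my)` is taken in the
#' tangent plane spanned by `mx = (n x ez)/|n x ez|` and `my = mx x n`, and
#' the result is renormalized. With `Dphi = 0` the polarity is unchanged; the
#' stationary distribution is uniform on the sphere.
#'
#' @param n polarity unit 3-vector.
#' @param dt time step, min.
#' @param Dphi polarity noise intensity, 1/min.
#' @param xi two standard-normal draws (supplied so the step is a pure
#'   function; defaults to fresh draws).
#' @return updated unit 3-vector.
#' @export
polarity_step <- function(n, dt, Dphi, xi = stats::rnorm(2)) {
  stopifnot(length(n) == 3L, length(xi) == 2L)
  nn <- sqrt(sum(n^2))
  if (abs(nn - 1) > 1e-9) stop("'n' must be a unit vector", call. = FALSE)
  cpp_polarity_step(as.numeric(n), dt, Dphi, xi[1], xi[2])
}

#' Pairwise repulsion force
#'
#' Linear elastic volume exclusion: zero beyond the cell diameter `dc`,
#' magnitude `mu (1 - d/dc)` directed from cell j to cell i otherwise.
#' Coincident cells (`d = 0`) are pushed apart along a direction derived
#' deterministically from the pair ids and seed.
#'
#' @param xi,xj positions of cells i and j, 3-vectors (um).
#' @param mu repulsion coefficient, um/min.
#' @param dc cell diameter, um.
#' @param ids integer pair of cell ids (tie-break for coincident cells).
#' @param seed integer seed entering the tie-break.
#' @return force on cell i, 3-vector (um/min); the force on j is its negative.
#' @export
pair_force <- function(xi, xj, mu = 8.71, dc = 11, ids = c(0L, 1L), seed = 1L) {
  cpp_pair_force(as.numeric(xi), as.numeric(xj), mu, dc,
                 as.integer(ids[1]), as.integer(ids[2]), as.integer(seed))
}

#' Net overdamped velocity of every cell
#'
#' Assembles the four terms of the equation of motion - advection, intrinsic
#' motility `v0(x) n`, the sum of pairwise repulsions, and the boundary
#' force - for a set of active cells. `method = "grid"` uses a uniform
#' spatial hash with bin size `dc` (exact cutoff semantics); `"allpairs"` is
#' the brute-force reference.
#'
#' @param positions n x 3 matrix of cell positions (um).
#' @param polarity n x 3 matrix of unit polarity vectors.
#' @param geom a [geometry_params()] object.
#' @param params a [mechanics_params()] object.
#' @param xa anterior-end position, um.
#' @param t simulation time, min.
#' @param r current tube radius, um.
#' @param method neighbor search method.
#' @param anterior_wall include the relaxation wall at `x = xa`?
#' @param seed integer seed for the coincident-pair tie-break.
#' @return n x 3 matrix of velocities (um/min).
#' @export
net_velocities <- function(positions, polarity, geom, params, xa = 0, t = 0,
                           r = geom$r0, method = c("grid", "allpairs"),
                           anterior_wall = FALSE, seed = 1L) {
  method <- match.arg(method)
  vp <- if (t < params$tg) params$vp_early else params$vp_late
  cpp_net_velocities(.as_pos_matrix(positions), .as_pos_matrix(polarity),
                     unclass(geom), unclass(params), xa, r, vp,
                     method == "grid", isTRUE(anterior_wall), as.integer(seed))
}
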