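# Phase-oscillator layer: frequency profile, coupling schedule, one-step
# phase increment, anterior arrest.

#' Autonomous frequency profile along the axis
#'
#' `omega(x) = omega0 * U(chi)` with
#' `U(chi) = sigma + (1 - sigma) (1 - exp(-k chi)) / (1 - exp(-k))` and
#' `chi = (x - xa)/L`; `U(0) = sigma`, `U(1) = 1`, monotone increasing toward
#' the posterior. `k = 0` uses the linear limit `U = sigma + (1 - sigma) chi`.
#'
#' @param x axial position(s), um.
#' @param xa anterior-end position, um.
#' @param L current PSM length, um.
#' @param params a [phase_params()] object.
#' @return frequency(ies), rad/min.
#' @export
frequency_profile <- function(x, xa, L, params) {
  chi <- (x - xa) / L
  params$omega0 * cpp_frequency_factor(as.numeric(chi), params$sigma, params$k)
}

#' Coupling-strength schedule
#'
#' Zero before the washout time (Notch inhibition), then the linear ramp
#' `kappas * t + kappa0`.
#'
#' @param t time(s), min.
#' @param params a [phase_params()] object.
#' @return coupling strength(s), 1/min.
#' @export
coupling_strength <- function(t, params) {
  k <- cpp_coupling_strength(as.numeric(t), params$t_washout, params$kappas,
                             params$kappa0)
  if (any(k < 0)) stop("negative coupling strength: invalid parameterization",
                       call. = FALSE)
  k
}

#' One Euler-Maruyama phase increment
#'
#' `dtheta = [omega + (kappa/n) sum sin(theta_j - theta_i)] dt +
#' sqrt(2 Dtheta dt) xi`, where the sum runs over the `n` supplied neighbor
#' phases (no coupling if there are none). The returned phase is wrapped to
#' \[0, 2 pi).
#'
#' @param theta phase of the focal cell, rad.
#' @param theta_neighbors phases of cells within the interaction range, rad.
#' @param omega autonomous frequency at the cell's position, rad/min.
#' @param kappa coupling strength, 1/min.
#' @param dt time step, min.
#' @param Dtheta phase noise intensity, 1/min.
#' @param xi a standard-normal draw (default: fresh draw).
#' @return updated phase in \[0, 2 pi).
#' @export
phase_increment <- function(theta, theta_neighbors, omega, kappa, dt,
                            Dtheta = 0, xi = stats::rnorm(1)) {
  n <- length(theta_neighbors)
  coup <- if (n > 0) kappa / n * sum(sin(theta_neighbors - theta)) else 0
  (theta + (omega + coup) * dt + sqrt(2 * Dtheta * dt) * xi) %% (2 * pi)
}

#' Arrest oscillators anterior to the PSM
#'
#' Cells with `x < xa` have left the PSM: their phase is frozen (the arrested
#' stripe pattern represents segment boundaries) and they are advected at the
#' anterior-end speed, excluded from force and coupling sums. This helper
#' applies the flagging rule to a cell table; inside [run_simulation()] the
#' same rule is applied every step.
#'
#' @param cells data.frame with at least columns `x` and `arrested` (0/1).
#' @param xa anterior-end position, um.
#' @return the table with `arrested` set for every cell with `x < xa`.
#' @export
arrest_anterior <- function(cells, xa) {
  cells$arrested[cells$x < xa] <- 1L
  cells
}
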