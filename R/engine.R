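# Simulation driver: initialization, Euler-Maruyama stepping (in C++),
# result assembly, and the anterior-period calibration used with PSM
# shortening.

.engine_args <- function(config, seed) {
  list(geom = unclass(config$geometry),
       mech = unclass(config$mechanics),
       phase = unclass(config$phase),
       program = list(ua = config$program$ua, sr = config$program$sr,
                      rho0 = config$program$rho0, zeta = config$program$zeta),
       dt = config$dt, duration = config$duration,
       relax_minutes = config$relax_minutes,
       obs_dt = config$obs_dt, profile_dt = config$profile_dt,
       snapshot_dt = config$snapshot_dt,
       arrested_window = config$arrested_window,
       post_window = config$posterior_window,
       M = config$detection$M,
       init_random = if (config$init_phase == "random_phase") 1L else 0L,
       theta0 = config$phase$theta_set,
       seed = as.double(seed),
       keep_snapshots = config$keep_snapshots)
}

.snap_to_df <- function(m) {
  df <- as.data.frame(m)
  df$id <- as.integer(df$id)
  df$arrested <- as.integer(df$arrested)
  df
}

#' Run a full tissue simulation
#'
#' Places `round(rho0 x volume)` cells uniformly in the U-shaped domain,
#' relaxes the packing mechanically (no advection, wall at `x = xa`), assigns
#' phases according to the initial-condition tag, and integrates the coupled
#' mechanics + phase dynamics with the Euler-Maruyama method at the
#' configured `dt`. The run records, at `obs_dt` cadence, the local order
#' `Z(t, xa)` and first-slice mean phase for both sides, the circular mean
#' phase near the posterior tip, and tissue scalars; axial order-parameter
#' profiles at `profile_dt`; optional full snapshots; an event log of cell
#' arrests and insertions; and the final state including retained arrested
#' cells.
#'
#' Runs are bit-reproducible for a given `(config, seed)`: all noise comes
#' from per-channel counter-seeded streams, so e.g. switching phase noise off
#' does not shift the polarity draws.
#'
#' @param config a [run_config()] or [preset_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `psm_run`: list with elements `status`
#'   (`"ok"`, `"psm_consumed"` or `"diverged"`), `series` (boundary and
#'   tissue time series), `profile` (times, x offsets and per-side Z and
#'   mean-phase matrices), `snapshots` + `snapshot_times`, `events`, `final`
#'   (cell table) and `config`, `seed`.
#' @examples
#' cfg <- run_config(geometry = geometry_params(r0 = 12, R = 25, L = 120),
#'                   duration = 5, init_phase = "synchronized", seed = 1)
#' run <- run_simulation(cfg)
#' head(run$series)
#' @export
run_simulation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "psm_config"))
  if (config$phase$tune_Ta && config$program$ua > 0)
    config$phase$omega0 <- tune_anterior_period(config)
  res <- cpp_run(.engine_args(config, seed))
  if (res$status == "diverged")
    stop("simulation diverged: non-finite position or phase", call. = FALSE)
  prof <- list(times = res$profile_times,
               x_offset = (seq_len(ncol(res$profile_Z_left)) - 1L) * config$mechanics$dc,
               Z_left = res$profile_Z_left, Z_right = res$profile_Z_right,
               psi_left = res$profile_psi_left, psi_right = res$profile_psi_right)
  out <- list(status = res$status,
              series = res$series,
              profile = prof,
              snapshot_times = res$snapshot_times,
              snapshots = lapply(res$snapshots, .snap_to_df),
              events = res$events,
              final = .snap_to_df(res$final),
              xa_final = res$xa_final,
              r_final = res$r_final,
              config = config,
              seed = as.integer(seed))
  class(out) <- "psm_run"
  out
}

#' Initialize a tissue without advancing time
#'
#' Equivalent to running the configuration with `duration = 0`: random
#' placement at the target density, mechanical relaxation, phase assignment.
#'
#' @inheritParams run_simulation
#' @return A `psm_run` whose `final` element is the initial state.
#' @export
initialize_tissue <- function(config, seed = config$seed) {
  config$duration <- 0
  config$phase$tune_Ta <- FALSE
  run_simulation(config, seed)
}

#' Calibrate `omega0` so the measured anterior period equals `Ta`
#'
#' When the PSM shortens, kinematic waves travel toward an approaching
#' anterior boundary and the period read out at `xa` is Doppler-shifted below
#' the posterior period `2 pi / omega0`. This routine bisects on `omega0`
#' using short deterministic runs (no phase noise, synchronized start) until
#' the mean interval between successive boundary-setting phase crossings at
#' `xa` is within `tol` of `Ta`.
#'
#' @param config a `psm_config` with `program$ua > 0`.
#' @param tol relative tolerance on the anterior period (default 1%).
#' @param probe_minutes duration of each probe run, min; the first half is
#'   discarded as the wave-formation transient (kinematic waves need about
#'   one transit time `L/va` to establish, during which the anterior period
#'   reads long).
#' @param max_iter maximum refinement iterations.
#' @return calibrated `omega0`, rad/min.
#' @export
tune_anterior_period <- function(config, tol = 0.01, probe_minutes = 300,
                                 max_iter = 8) {
  Ta <- config$phase$Ta
  probe <- config
  probe$phase$tune_Ta <- FALSE
  probe$phase$Dtheta <- 0
  probe$init_phase <- "synchronized"
  probe$duration <- probe_minutes
  probe$keep_snapshots <- FALSE

  measure <- function(om) {
    probe$phase$omega0 <- om
    run <- run_simulation(probe, seed = 1L)
    s <- run$series
    psi <- s$psi1_left # the profile is left-right symmetric; one side suffices
    ok <- !is.na(psi)
    tau <- detect_boundary_times(s$time[ok], psi[ok],
                                 theta = config$phase$theta_set, Ta = Ta)
    tau <- tau[tau > probe_minutes / 2]
    if (length(tau) < 3) return(NA_real_)
    mean(diff(tau))
  }

  # the measured period scales close to 1/omega0, so proportional updates
  # converge in a few probes
  om <- config$phase$omega0
  for (i in seq_len(max_iter)) {
    Tm <- measure(om)
    if (is.na(Tm)) stop("calibration probe produced too few boundary events",
                        call. = FALSE)
    if (abs(Tm - Ta) / Ta <= tol) return(om)
    om <- om * Tm / Ta
  }
  om
}

#' @export
print.psm_run <- function(x, ...) {
  s <- x$series
  cat(sprintf("psmclock run (%s): %g min simulated, seed %d\n",
              x$status, max(s$time), x$seed))
  cat(sprintf("  cells: %d active at end (+%d arrested retained)\n",
              sum(x$final$arrested == 0), sum(x$final$arrested == 1)))
  cat(sprintf("  final Z(t, xa): left %.3f, right %.3f\n",
              tail(s$Z_left, 1), tail(s$Z_right, 1)))
  invisible(x)
}
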