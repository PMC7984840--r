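# Parameter blocks and run configuration.
#
# Defaults reproduce the study conditions of the model: a constant U-shaped
# tissue with tube radius 25 um, torus core radius 50 um and initial PSM
# length 325 um; cell diameter 11 um; anterior advection speed chosen so that
# one segment (advection speed x anterior period) spans ~5 cell diameters.

.check_num <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  as.numeric(x)
}

#' Geometry of the U-shaped PSM/tailbud domain
#'
#' The left and right PSM are tubes of radius `r0` with axes parallel to the
#' x-axis at (y, z) = (Yc - R, Zc) and (Yc + R, Zc); the tailbud is a half
#' torus of core radius `R` joining them at x >= Xc. The posterior tip sits at
#' `Lx = Xc + R + r0` and the tissue occupies y in \[0, 2R + 2 r0\] and
#' z in \[0, 2 r0\] with Yc = R + r0, Zc = r0.
#'
#' @param r0 tube (PSM) radius, um.
#' @param R torus core radius (tailbud size), um.
#' @param L initial PSM length `Lx - xa(0)` with `xa(0) = 0`, um.
#' @return A list of class `psm_geometry` with fields `r0`, `R`, `Xc`, `Yc`,
#'   `Zc`, `Lx`.
#' @examples
#' g <- geometry_params()
#' g$Lx - g$Xc # = R + r0: the posterior tip sits on the torus outer edge
#' @export
geometry_params <- function(r0 = 25, R = 50, L = 325) {
  r0 <- .check_num(r0, "r0", 0, strict_lower = TRUE)
  R <- .check_num(R, "R", 0, strict_lower = TRUE)
  L <- .check_num(L, "L", 0, strict_lower = TRUE)
  if (L <= R + r0)
    stop("PSM length L must exceed R + r0 (tubes must have positive length)",
         call. = FALSE)
  g <- list(r0 = r0, R = R, Xc = L - R - r0, Yc = R + r0, Zc = r0, Lx = L)
  class(g) <- "psm_geometry"
  g
}

#' Cell mechanics parameters
#'
#' @param mu repulsion coefficient, um/min.
#' @param dc cell diameter = interaction cutoff, um.
#' @param mub boundary-force coefficient, um/min.
#' @param rb boundary-force decay length, um.
#' @param vs maximum intrinsic cell speed (posterior tip), um/min.
#' @param Xv motility-gradient length scale, fraction of PSM length.
#' @param h motility-gradient steepness exponent.
#' @param Dphi polarity noise intensity, 1/min.
#' @param va advection speed at the anterior end, um/min. The default
#'   55/30 um/min makes one segment (va x 30 min) span 55 um = 5 dc.
#' @param xq anterior/posterior split of the advection profile (fraction of L).
#' @param vp_early,vp_late posterior advection parameter before and after the
#'   switching time `tg`, um/min. Equal values give a time-constant pattern.
#' @param tg advection-pattern switching time, min.
#' @return A list of class `psm_mechanics`.
#' @export
mechanics_params <- function(mu = 8.71, dc = 11, mub = 20, rb = 1,
                             vs = 1.0, Xv = 0.4, h = 3, Dphi = 0.1,
                             va = 55 / 30, xq = 0.5,
                             vp_early = 0.3 * va, vp_late = va, tg = 270) {
  p <- list(
    mu = .check_num(mu, "mu", 0), dc = .check_num(dc, "dc", 0, strict_lower = TRUE),
    mub = .check_num(mub, "mub", 0), rb = .check_num(rb, "rb", 0, strict_lower = TRUE),
    vs = .check_num(vs, "vs", 0), Xv = .check_num(Xv, "Xv", 0, strict_lower = TRUE),
    h = .check_num(h, "h", 0), Dphi = .check_num(Dphi, "Dphi", 0),
    va = .check_num(va, "va", 0), xq = .check_num(xq, "xq", 0, 1, strict_lower = TRUE),
    vp_early = .check_num(vp_early, "vp_early", 0),
    vp_late = .check_num(vp_late, "vp_late", 0),
    tg = .check_num(tg, "tg", 0))
  if (p$xq >= 1) stop("'xq' must be < 1", call. = FALSE)
  class(p) <- "psm_mechanics"
  p
}

#' Phase-oscillator parameters
#'
#' @param omega0 angular frequency at the posterior tip, rad/min (2 pi / 30).
#' @param sigma anterior/posterior frequency ratio, in (0, 1].
#' @param k shape of the frequency profile (0 gives the linear limit).
#' @param Dtheta phase noise intensity, 1/min.
#' @param kappa0 base coupling strength after washout, 1/min.
#' @param kappas coupling ramp slope, 1/min^2.
#' @param t_washout washout time: coupling is 0 before it, min.
#' @param theta_set boundary-setting phase (stripe phase), rad.
#' @param Ta anterior period of oscillation (segmentation period), min.
#' @param tune_Ta if `TRUE` and the PSM shortens, `omega0` is recalibrated
#'   before the run so the measured anterior period equals `Ta` (the Doppler
#'   effect of the approaching anterior boundary otherwise shortens it).
#' @return A list of class `psm_phase`.
#' @export
phase_params <- function(omega0 = 2 * pi / 30, sigma = 0.7, k = 3,
                         Dtheta = 0.0013, kappa0 = 0.07, kappas = 0,
                         t_washout = 0, theta_set = 3 * pi / 2, Ta = 30,
                         tune_Ta = FALSE) {
  p <- list(
    omega0 = .check_num(omega0, "omega0", 0, strict_lower = TRUE),
    sigma = .check_num(sigma, "sigma", 0, 1, strict_lower = TRUE),
    k = .check_num(k, "k", 0),
    Dtheta = .check_num(Dtheta, "Dtheta", 0),
    kappa0 = .check_num(kappa0, "kappa0", 0),
    kappas = .check_num(kappas, "kappas"),
    t_washout = .check_num(t_washout, "t_washout", 0),
    theta_set = .check_num(theta_set, "theta_set", 0, 2 * pi),
    Ta = .check_num(Ta, "Ta", 0, strict_lower = TRUE),
    tune_Ta = isTRUE(tune_Ta))
  class(p) <- "psm_phase"
  p
}

#' Tissue-program parameters
#'
#' @param ua speed of the anterior end (PSM shortening rate), um/min; the
#'   anterior end sits at `xa(t) = ua t` and `L(t) = Lx - ua t`.
#' @param c segment-length constant in `va + ua = c`, um/min; if `NULL` it is
#'   taken as the mechanics default `va` so a constant tissue keeps its speed.
#' @param sr radius shrink rate, um/min (`r(t) = r0 - sr t`, floored at 2 dc).
#' @param rho0 target cell density, cells/um^3 (998 cells in a
#'   110 x 110 x 55 um^3 box give ~0.0015).
#' @param zeta anterior margin in which no cells are inserted, um.
#' @return A list of class `psm_program`.
#' @export
program_params <- function(ua = 0, c = NULL, sr = 0, rho0 = 0.0015, zeta = 100) {
  ua <- .check_num(ua, "ua", 0)
  if (!is.null(c)) {
    c <- .check_num(c, "c", 0, strict_lower = TRUE)
    if (c <= ua) stop("'c' must exceed 'ua' so that va = c - ua > 0", call. = FALSE)
  }
  p <- list(ua = ua, c = c, sr = .check_num(sr, "sr", 0),
            rho0 = .check_num(rho0, "rho0", 0, strict_lower = TRUE),
            zeta = .check_num(zeta, "zeta", 0))
  class(p) <- "psm_program"
  p
}

#' Segment-boundary detection parameters
#'
#' @param Zc local-order threshold separating normal from defective
#'   boundaries.
#' @param eta confirmation window over which `Z(t, xa)` must stay above `Zc`,
#'   min.
#' @param Delta tolerance used when numbering a boundary from its detection
#'   time.
#' @param M number of consecutive slices averaged into the local order.
#' @param dx_slice slice width, um; defaults to the cell diameter.
#' @return A list of class `psm_detection`.
#' @export
detection_params <- function(Zc = 0.85, eta = 4, Delta = 0.3, M = 5,
                             dx_slice = 11) {
  p <- list(Zc = .check_num(Zc, "Zc", 0, 1, strict_lower = TRUE),
            eta = .check_num(eta, "eta", 0, strict_lower = TRUE),
            Delta = .check_num(Delta, "Delta", 0, 0.5, strict_lower = TRUE),
            M = as.integer(.check_num(M, "M", 1)),
            dx_slice = .check_num(dx_slice, "dx_slice", 0, strict_lower = TRUE))
  if (p$Delta >= 0.5) stop("'Delta' must be < 0.5", call. = FALSE)
  class(p) <- "psm_detection"
  p
}

#' Phase-vorticity detector parameters
#'
#' @param slab_thickness thickness of the projection slices, um.
#' @param dx,dw grid spacing along x and along the transverse coordinate, um.
#' @param delta_l inner radius of the sampling ring, um.
#' @param l radial width of the sampling ring, um.
#' @param alpha correlation threshold for accepting a linear phase increase
#'   around the ring; calibrated on noiseless planted vortices so that
#'   detections cluster within ~2 grid cells of the core while uniform and
#'   pure-gradient fields give none.
#' @param psi_min minimum winding fraction `(theta_hat_5 - theta_hat_0)/2 pi`
#'   accepted as a vortex (guards against fluctuation-induced false
#'   positives).
#' @return A list of class `psm_vorticity`. The ring is always subdivided into
#'   six angular sectors.
#' @export
vorticity_params <- function(slab_thickness = 20, dx = 5, dw = 2,
                             delta_l = 5.5, l = 14, alpha = 0.97,
                             psi_min = 0.6) {
  p <- list(slab_thickness = .check_num(slab_thickness, "slab_thickness", 0, strict_lower = TRUE),
            dx = .check_num(dx, "dx", 0, strict_lower = TRUE),
            dw = .check_num(dw, "dw", 0, strict_lower = TRUE),
            delta_l = .check_num(delta_l, "delta_l", 0, strict_lower = TRUE),
            l = .check_num(l, "l", 0, strict_lower = TRUE),
            n_sectors = 6L,
            alpha = .check_num(alpha, "alpha", 0, 1, strict_lower = TRUE),
            psi_min = .check_num(psi_min, "psi_min", 0, 1))
  class(p) <- "psm_vorticity"
  p
}

#' Constants of the vorticity correlation index
#'
#' The detector regresses the cyclically permuted sector means against the
#' sector index i = 0..5; the index has mean 5/2 and variance
#' sum((i - 5/2)^2)/6 = 35/12.
#'
#' @return list with `index_mean` (5/2) and `index_var` (35/12).
#' @export
vorticity_constants <- function() {
  list(index_mean = 5 / 2, index_var = 35 / 12)
}

#' Assemble a full run configuration
#'
#' @param geometry,mechanics,phase,program,detection,vorticity parameter
#'   blocks; see the corresponding `*_params()` constructors.
#' @param dt integration time step, min.
#' @param duration simulated time, min.
#' @param seed integer seed for the run's random streams.
#' @param init_phase `"random_phase"` (resynchronization; phases i.i.d.
#'   uniform) or `"synchronized"` (all phases at `theta_set`).
#' @param relax_minutes duration of the mechanical relaxation performed on the
#'   random initial packing (no advection, wall at x = xa), min.
#' @param obs_dt cadence of the boundary series (`Z(t, xa)`, mean phase), min.
#' @param profile_dt cadence of the axial order-parameter profiles, min.
#' @param snapshot_dt cadence of full state snapshots, min (0 disables
#'   intermediate snapshots; initial and final states are always kept).
#' @param keep_snapshots store intermediate snapshots?
#' @param arrested_window how long arrested (segmented) cells are retained in
#'   the state after arrest, min.
#' @param posterior_window axial depth (from the posterior tip) of the cell
#'   population whose circular mean phase is recorded, um.
#' @return A list of class `psm_config`.
#' @examples
#' cfg <- run_config(duration = 30, seed = 1)
#' cfg$phase$omega0 * cfg$phase$Ta / (2 * pi) # one cycle per anterior period
#' @export
run_config <- function(geometry = geometry_params(),
                       mechanics = mechanics_params(),
                       phase = phase_params(),
                       program = program_params(),
                       detection = detection_params(dx_slice = mechanics$dc),
                       vorticity = vorticity_params(),
                       dt = 0.01, duration = 600, seed = 1L,
                       init_phase = c("random_phase", "synchronized"),
                       relax_minutes = 10, obs_dt = 0.5, profile_dt = 2,
                       snapshot_dt = 0, keep_snapshots = FALSE,
                       arrested_window = 150, posterior_window = 20) {
  init_phase <- match.arg(init_phase)
  stopifnot(inherits(geometry, "psm_geometry"), inherits(mechanics, "psm_mechanics"),
            inherits(phase, "psm_phase"), inherits(program, "psm_program"),
            inherits(detection, "psm_detection"), inherits(vorticity, "psm_vorticity"))
  dt <- .check_num(dt, "dt", 0, strict_lower = TRUE)
  duration <- .check_num(duration, "duration", 0)
  # segment-length constraint va + ua = c
  if (!is.null(program$c)) {
    mechanics$va <- program$c - program$ua
    if (mechanics$va <= 0) stop("program$c - program$ua must be positive", call. = FALSE)
  } else if (program$ua > 0) {
    # keep the segment length by default: c = default anterior speed
    cc <- mechanics$va
    mechanics$va <- cc - program$ua
    program$c <- cc
    if (mechanics$va <= 0) stop("'ua' too large for the advection speed", call. = FALSE)
  }
  # coupling must stay non-negative over the run
  kend <- phase$kappas * duration + phase$kappa0
  if (kend < 0 || phase$kappa0 < 0)
    stop("coupling strength becomes negative during the run", call. = FALSE)
  cfg <- list(geometry = geometry, mechanics = mechanics, phase = phase,
              program = program, detection = detection, vorticity = vorticity,
              dt = dt, duration = duration, seed = as.integer(seed),
              init_phase = init_phase,
              relax_minutes = .check_num(relax_minutes, "relax_minutes", 0),
              obs_dt = .check_num(obs_dt, "obs_dt", 0, strict_lower = TRUE),
              profile_dt = .check_num(profile_dt, "profile_dt", 0, strict_lower = TRUE),
              snapshot_dt = .check_num(snapshot_dt, "snapshot_dt", 0),
              keep_snapshots = isTRUE(keep_snapshots),
              arrested_window = .check_num(arrested_window, "arrested_window", 0),
              posterior_window = .check_num(posterior_window, "posterior_window", 0))
  class(cfg) <- "psm_config"
  cfg
}

#' Named protocol presets
#'
#' * `fig3_constant`: resynchronization in a constant tissue (random initial
#'   phases, uniform strain rate, coupling on from t = 0).
#' * `fig4b_shortening`: as above with linear PSM shortening (`ua > 0`,
#'   segment length held constant through `va + ua = c`).
#' * `fig4c_advection_switch`: advection pattern switches from anterior-loaded
#'   strain (`vp = 0.3 va`) to posterior-loaded (`vp = va`) at `tg`.
#' * `fig4e_combined`: shortening + advection switch + linearly increasing
#'   coupling strength (doubling by ~450 min).
#' * `wildtype`: synchronized initial condition, constant tissue (control).
#'
#' @param name preset name.
#' @param ... overrides passed to [run_config()] (e.g. `duration`, `seed`).
#' @return A `psm_config`.
#' @export
preset_config <- function(name = c("fig3_constant", "fig4b_shortening",
                                   "fig4c_advection_switch", "fig4e_combined",
                                   "wildtype"), ...) {
  name <- match.arg(name)
  va0 <- 55 / 30
  ua_short <- 0.36 # shrinks L by ~30% over 9 somite stages (270 min)
  base <- switch(name,
    fig3_constant = list(
      mechanics = mechanics_params(vp_early = va0, vp_late = va0, tg = 0),
      phase = phase_params(), init_phase = "random_phase"),
    fig4b_shortening = list(
      mechanics = mechanics_params(vp_early = va0, vp_late = va0, tg = 0),
      phase = phase_params(tune_Ta = TRUE),
      program = program_params(ua = ua_short, c = va0),
      init_phase = "random_phase"),
    fig4c_advection_switch = list(
      mechanics = mechanics_params(vp_early = 0.3 * va0, vp_late = va0, tg = 270),
      phase = phase_params(), init_phase = "random_phase"),
    fig4e_combined = list(
      mechanics = mechanics_params(vp_early = 0.3 * va0, vp_late = va0, tg = 270),
      phase = phase_params(kappas = 0.07 / 450, tune_Ta = TRUE),
      program = program_params(ua = ua_short, c = va0),
      init_phase = "random_phase"),
    wildtype = list(
      mechanics = mechanics_params(vp_early = va0, vp_late = va0, tg = 0),
      phase = phase_params(), init_phase = "synchronized"))
  args <- utils::modifyList(base, list(...))
  do.call(run_config, args)
}

#' Analytic region volumes
#'
#' Tube volume is `pi r^2 (Xc - xa)`; the half-torus volume is
#' `pi^2 R r^2` (half of the full-torus `2 pi^2 R r^2`).
#'
#' @param geom a [geometry_params()] object.
#' @param xa current anterior-end position, um.
#' @param region one of `"left_psm"`, `"right_psm"`, `"tailbud"`.
#' @param r current tube radius (defaults to `geom$r0`), um.
#' @return volume in um^3.
#' @export
region_volume <- function(geom, xa = 0, region = c("left_psm", "right_psm", "tailbud"),
                          r = geom$r0) {
  region <- match.arg(region)
  if (xa >= geom$Xc) stop("PSM consumed: xa >= Xc leaves no tube volume", call. = FALSE)
  switch(region,
         left_psm = ,
         right_psm = pi * r^2 * (geom$Xc - xa),
         tailbud = pi^2 * geom$R * r^2)
}

#' @export
print.psm_config <- function(x, ...) {
  g <- x$geometry
  cat("psmclock run configuration\n")
  cat(sprintf("  geometry: r0 = %g um, R = %g um, L(0) = %g um\n", g$r0, g$R, g$Lx))
  cat(sprintf("  phases:   omega0 = %.4f rad/min, sigma = %g, kappa0 = %g /min, Dtheta = %g /min\n",
              x$phase$omega0, x$phase$sigma, x$phase$kappa0, x$phase$Dtheta))
  cat(sprintf("  program:  ua = %g um/min, sr = %g um/min, rho0 = %g /um^3\n",
              x$program$ua, x$program$sr, x$program$rho0))
  cat(sprintf("  run:      dt = %g min, duration = %g min, init = %s, seed = %d\n",
              x$dt, x$duration, x$init_phase, x$seed))
  invisible(x)
}
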