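# Engine: initialization, determinism, stepping accuracy, degenerate
# configurations.

test_that("synchronized initialization sets every phase to the stripe phase", {
  cfg <- tiny_config(duration = 0, init_phase = "synchronized", seed = 3)
  run <- initialize_tissue(cfg)
  expect_true(all(run$final$theta == 3 * pi / 2))
  # cell number matches the density target
  g <- cfg$geometry
  vol <- 2 * region_volume(g, 0, "left_psm") + region_volume(g, 0, "tailbud")
  expect_equal(nrow(run$final), round(cfg$program$rho0 * vol))
})

test_that("random initialization is circularly uniform (Rayleigh bound)", {
  cfg <- run_config(geometry = geometry_params(r0 = 20, R = 40, L = 260),
                    duration = 0, init_phase = "random_phase", seed = 11)
  run <- initialize_tissue(cfg)
  th <- run$final$theta
  n <- length(th)
  expect_gt(n, 800)
  R <- sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
  # E[R] ~ sqrt(pi/(4 n)); 0.06 is ~2 sigma for n ~ 1000
  expect_lt(R, 0.06)
})

test_that("relaxation removes most initial overlaps", {
  cfg <- run_config(geometry = geometry_params(r0 = 15, R = 30, L = 160),
                    duration = 0, seed = 5)
  run <- initialize_tissue(cfg)
  p <- as.matrix(run$final[, c("x", "y", "z")])
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  frac_overlap <- mean(apply(d, 1, min) < 0.5 * cfg$mechanics$dc)
  expect_lt(frac_overlap, 0.01)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  cfg <- tiny_config(duration = 10, init_phase = "random_phase", seed = 7)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$series, r2$series)
  r3 <- run_simulation(cfg, seed = 8)
  expect_false(identical(r1$final$theta, r3$final$theta))
})

test_that("zero-dynamics configuration: frozen positions, free-running phases", {
  # all force terms off, no noise: positions fixed, phases advance by
  # omega dt exactly
  cfg <- run_config(
    geometry = geometry_params(r0 = 12, R = 25, L = 130),
    mechanics = mechanics_params(vs = 0, Dphi = 0, va = 1e-9, vp_early = 0,
                                 vp_late = 0, tg = 0, mu = 0, mub = 0),
    phase = phase_params(Dtheta = 0, kappa0 = 0, sigma = 1),
    program = program_params(rho0 = 3e-4),
    duration = 5, relax_minutes = 0, init_phase = "synchronized", seed = 2)
  run0 <- initialize_tissue(cfg)
  run <- run_simulation(cfg)
  same <- intersect(run0$final$id, run$final$id)
  p0 <- run0$final[match(same, run0$final$id), ]
  p1 <- run$final[match(same, run$final$id), ]
  active <- p1$arrested == 0 & p0$x > 1 # cells that never crossed xa
  expect_lt(max(abs(p1$x[active] - p0$x[active])), 1e-6)
  expect_lt(max(abs(p1$y[active] - p0$y[active])), 1e-6)
  th_expect <- (p0$theta[active] + cfg$phase$omega0 * 5) %% (2 * pi)
  expect_equal(p1$theta[active], th_expect, tolerance = 1e-6)
})

test_that("duration zero yields the initial snapshot only", {
  cfg <- tiny_config(duration = 0, seed = 1)
  run <- run_simulation(cfg)
  expect_equal(max(run$series$time), 0)
  expect_equal(nrow(run$series), 1L)
})

test_that("halving dt halves the Euler error of phase trajectories", {
  # coupled phase dynamics on frozen cell positions (a smooth deterministic
  # ODE): Euler is first order, so the 10-min error vs a fine-dt reference
  # scales ~ dt. (With mechanics on, particle-trajectory chaos would mask
  # the order of convergence.)
  base <- function(dt) {
    cfg <- run_config(
      geometry = geometry_params(r0 = 12, R = 25, L = 130),
      mechanics = mechanics_params(vs = 0, Dphi = 0, va = 1e-9, vp_early = 0,
                                   vp_late = 0, tg = 0, mu = 0, mub = 0),
      phase = phase_params(Dtheta = 0, kappa0 = 0.3),
      dt = dt, duration = 10, relax_minutes = 0,
      init_phase = "random_phase", seed = 9)
    run <- run_simulation(cfg)
    run$final[run$final$arrested == 0, c("id", "theta")]
  }
  ref <- base(0.0025)
  coarse <- base(0.02)
  mid <- base(0.01)
  derr <- function(a) {
    m <- merge(ref, a, by = "id")
    d <- (m$theta.x - m$theta.y + pi) %% (2 * pi) - pi
    sqrt(mean(d^2))
  }
  ratio <- derr(coarse) / derr(mid)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("no active cell escapes the domain beyond the boundary-force skin", {
  cfg <- tiny_config(duration = 20, seed = 13)
  run <- run_simulation(cfg)
  g <- cfg$geometry
  act <- run$final[run$final$arrested == 0, ]
  in_tube <- act$x < g$Xc
  rho_t <- pmin(sqrt((act$y - (g$Yc - g$R))^2 + (act$z - g$Zc)^2),
                sqrt((act$y - (g$Yc + g$R))^2 + (act$z - g$Zc)^2))
  expect_lt(max(rho_t[in_tube]), g$r0 + 5 * cfg$mechanics$rb)
  tor <- torus_coords(as.matrix(act[!in_tube, c("x", "y", "z")]), g)
  if (nrow(tor) > 0) expect_lt(max(tor$rho), g$r0 + 5 * cfg$mechanics$rb)
})

test_that("kinematic waves: anterior phase lags accumulate from a synchronized start", {
  cfg <- run_config(geometry = geometry_params(r0 = 15, R = 30, L = 200),
                    phase = phase_params(Dtheta = 0),
                    mechanics = mechanics_params(Dphi = 0.1),
                    duration = 60, init_phase = "synchronized", seed = 4)
  run <- run_simulation(cfg)
  # crossing times of the stripe phase at increasing anterior distance must
  # increase toward the anterior (waves travel posterior -> anterior)
  prof <- run$profile
  i_t <- length(prof$times)
  psi <- prof$psi_left[i_t, ]
  ok <- !is.na(psi)
  # mean phase decreases from posterior to anterior after the transient
  u <- rev(psmclock:::.unwrap(rev(psi[ok]))) # unwrap from the posterior end
  expect_gt(u[length(u)] - u[1], 1) # posterior leads by > 1 rad
})
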