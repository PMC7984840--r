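# Tissue programs: shortening, radius schedule, density-controlled influx,
# segment-length constraint.

test_that("schedule formulas: anterior position and radius floor", {
  expect_equal(anterior_position(c(0, 10, 100), ua = 0), c(0, 0, 0))
  expect_equal(anterior_position(50, ua = 0.4), 20)
  expect_equal(radius_schedule(c(0, 40), sr = 0.05, r0 = 25), c(25, 23))
  expect_equal(radius_schedule(1000, sr = 0.05, r0 = 25), 22)  # floored at 2 dc
  expect_equal(radius_schedule(1000, sr = 0.05, r0 = 15), 15)  # floor <= r0
})

test_that("anterior end and PSM length schedules", {
  cfg0 <- tiny_config(duration = 10, seed = 1)
  run0 <- run_simulation(cfg0)
  expect_true(all(run0$series$xa == 0)) # ua = 0: constant tissue
  cfg <- run_config(geometry = geometry_params(r0 = 12, R = 25, L = 200),
                    program = program_params(ua = 0.5, c = 55 / 30 + 0.5),
                    duration = 20, init_phase = "synchronized", seed = 1)
  expect_equal(cfg$mechanics$va, 55 / 30) # va = c - ua
  run <- run_simulation(cfg)
  expect_equal(tail(run$series$xa, 1), 0.5 * 20, tolerance = 1e-9)
})

test_that("the run halts with 'psm_consumed' when shortening eats the PSM", {
  cfg <- run_config(geometry = geometry_params(r0 = 12, R = 25, L = 120),
                    program = program_params(ua = 2, c = 4),
                    duration = 60, init_phase = "synchronized", seed = 1)
  run <- run_simulation(cfg)
  expect_equal(run$status, "psm_consumed")
  # halt happens when the advancing anterior end reaches the tubes' end
  expect_lt(max(run$series$time), 60)
})

test_that("radius shrinkage keeps every active cell inside the new wall", {
  cfg <- run_config(geometry = geometry_params(r0 = 25, R = 30, L = 170),
                    program = program_params(sr = 0.05),
                    duration = 40, init_phase = "synchronized", seed = 6)
  run <- run_simulation(cfg)
  r_end <- run$r_final
  expect_equal(r_end, 25 - 0.05 * 40, tolerance = 1e-9)
  g <- cfg$geometry
  act <- run$final[run$final$arrested == 0, ]
  in_tube <- act$x < g$Xc
  rho <- pmin(sqrt((act$y - (g$Yc - g$R))^2 + (act$z - g$Zc)^2),
              sqrt((act$y - (g$Yc + g$R))^2 + (act$z - g$Zc)^2))
  # cells may press into the soft wall a little, never far beyond it
  expect_lt(max(rho[in_tube]), r_end + 5 * cfg$mechanics$rb)
})

test_that("density control keeps the active count stationary in a constant tissue", {
  cfg <- run_config(geometry = geometry_params(r0 = 15, R = 30, L = 200),
                    duration = 120, init_phase = "synchronized", seed = 8)
  run <- run_simulation(cfg)
  n0 <- run$series$n_active[1]
  expect_lt(max(abs(run$series$n_active - n0)) / n0, 0.05)
  # long-run density within 5% of the target
  g <- cfg$geometry
  vol <- 2 * region_volume(g, 0, "left_psm") + region_volume(g, 0, "tailbud")
  dens <- tail(run$series$n_active, 1) / vol
  expect_equal(dens, cfg$program$rho0, tolerance = 0.05)
})

test_that("insertions respect the anterior margin and the domain", {
  cfg <- run_config(geometry = geometry_params(r0 = 20, R = 40, L = 260),
                    duration = 60, init_phase = "synchronized", seed = 9)
  run <- run_simulation(cfg)
  ins <- run$events[run$events$type == 2, ]
  expect_gt(nrow(ins), 10)
  tube_ins <- ins[ins$region %in% c(1, 2), ]
  # xa = 0 throughout: tube insertions all posterior to the zeta margin
  expect_true(all(tube_ins$x > cfg$program$zeta))
  expect_true(all(tube_ins$x <= cfg$geometry$Xc))
  # arrests (removals) happen at the anterior end
  rem <- run$events[run$events$type == 1, ]
  expect_true(all(rem$x <= 0))
  # every insertion follows a removal event at the same time
  expect_true(all(ins$time %in% rem$time))
})

test_that("segment length is set by c * Ta independent of the shortening speed", {
  # arrested-stripe wavelength ~ c Ta for ua = 0 and ua > 0 with c fixed
  # score stripes arrested after the kinematic-wave transient (~L/va) has
  # passed, when the anterior period has settled at Ta
  mk <- function(ua) {
    run_config(
      geometry = geometry_params(r0 = 15, R = 30, L = 220),
      program = program_params(ua = ua, c = 1.2),
      phase = phase_params(Dtheta = 0),
      duration = 330, arrested_window = 120,
      init_phase = "synchronized", seed = 10)
  }
  w0 <- stripe_wavelength(run_simulation(mk(0)))$wavelength
  w1 <- stripe_wavelength(run_simulation(mk(0.2)))$wavelength
  expect_equal(w0, 1.2 * 30, tolerance = 0.1)
  expect_lt(abs(w1 - w0) / w0, 0.1)
})

test_that("anterior-period calibration compensates the shortening Doppler shift", {
  cfg <- run_config(geometry = geometry_params(r0 = 12, R = 25, L = 220),
                    program = program_params(ua = 0.3, c = 55 / 30),
                    phase = phase_params(Dtheta = 0, tune_Ta = TRUE),
                    duration = 150, init_phase = "synchronized", seed = 2)
  om <- tune_anterior_period(cfg, tol = 0.01)
  # with an approaching boundary the posterior frequency must be lowered
  expect_lt(om, cfg$phase$omega0)
  # and the calibrated run indeed shows Ta ~ 30 min at the anterior end
  cfg2 <- cfg; cfg2$phase$omega0 <- om; cfg2$phase$tune_Ta <- FALSE
  run <- run_simulation(cfg2)
  s <- run$series
  tau <- detect_boundary_times(s$time, s$psi1_left, Ta = 30)
  tau <- tau[tau > 60]
  expect_equal(mean(diff(tau)), 30, tolerance = 0.02 * 30)
})
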