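# Observables: slice/local order, boundary detection, classification,
# numbering, scoring, defect statistics, vorticity.

geom <- geometry_params()

cells_at <- function(x, theta, side = "left", geom. = geom, n = length(theta)) {
  y0 <- if (side == "left") 0 else 2 * geom.$R
  data.frame(x = x, y = y0 + runif(n, 0, 2 * geom.$r0),
             z = runif(n, 0, 2 * geom.$r0), theta = theta, arrested = 0L)
}

test_that("slice order: identical, antiphase and uniform-random phases", {
  set.seed(21)
  cc <- cells_at(rep(5, 40), rep(1.2, 40))
  so <- slice_order(cc, 0, "left", geom)
  expect_equal(so$Z, 1)
  expect_equal(so$psi, 1.2)
  # {0, pi} cancels
  cc2 <- cells_at(rep(5, 40), rep(c(0, pi), 20))
  expect_equal(slice_order(cc2, 0, "left", geom)$Z, 0, tolerance = 1e-12)
  # 1000 iid uniform phases: Rayleigh scale ~ sqrt(pi/(4 n))
  z <- replicate(20, {
    cc3 <- cells_at(rep(5, 1000), runif(1000, 0, 2 * pi))
    slice_order(cc3, 0, "left", geom)$Z
  })
  expect_lt(mean(z < 0.09), 1.01)           # sanity
  expect_gt(mean(z < 0.09), 0.9)            # ~Rayleigh: P(Z < 0.09) ~ 0.97
  # empty slice is flagged missing
  expect_true(is.na(slice_order(cc, 500, "left", geom)$Z))
})

test_that("local order stays high across a phase gradient, M = 1 degenerates", {
  set.seed(22)
  # each slice internally synchronized, phase varying across slices
  cc <- do.call(rbind, lapply(0:4, function(m)
    cells_at(rep(m * 11 + 5, 30), rep(m * 2 * pi / 5, 30))))
  expect_equal(local_order(cc, 0, "left", geom, M = 5), 1, tolerance = 1e-12)
  # fully random tissue: low local order with >= 30 cells per slice
  cc2 <- do.call(rbind, lapply(0:4, function(m)
    cells_at(rep(m * 11 + 5, 60), runif(60, 0, 2 * pi))))
  expect_lt(local_order(cc2, 0, "left", geom, M = 5), 0.3)
  # M = 1 equals the slice modulus
  expect_equal(local_order(cc, 0, "left", geom, M = 1),
               slice_order(cc, 0, "left", geom)$Z)
})

test_that("boundary-time detection: linear phase, constants, jitter merging", {
  t <- seq(0, 200, by = 0.5)
  w0 <- 2 * pi / 30
  tau <- detect_boundary_times(t, (w0 * t) %% (2 * pi), theta = 3 * pi / 2, Ta = 30)
  expect_equal(tau, 22.5 + 30 * (seq_along(tau) - 1), tolerance = 1e-9)
  # constant series: no events
  expect_length(detect_boundary_times(t, rep(1, length(t))), 0)
  # a double-crossing jitter within Ta/2 yields a single event
  psi <- (w0 * t) %% (2 * pi)
  i0 <- which.min(abs(t - 23.5)) # just after the first crossing
  psi[i0] <- 3 * pi / 2 - 0.05   # dip back below, then recross
  tau2 <- detect_boundary_times(t, psi, theta = 3 * pi / 2, Ta = 30)
  expect_equal(length(tau2), length(tau))
  expect_lt(abs(tau2[1] - 22.5), 1)
})

test_that("boundary classification follows the strict windowed threshold", {
  t <- seq(0, 100, by = 0.5)
  expect_equal(classify_boundary(t, rep(1, length(t)), tau = 50), "normal")
  expect_equal(classify_boundary(t, rep(0.84, length(t)), tau = 50), "defective")
  # one dip inside the eta window spoils the boundary
  z <- rep(1, length(t))
  z[t == 36] <- 0.80 # window is [35, 39] for tau = 50
  expect_equal(classify_boundary(t, z, tau = 50), "defective")
  # dips outside the window are ignored
  z2 <- rep(1, length(t)); z2[t == 45] <- 0.5
  expect_equal(classify_boundary(t, z2, tau = 50), "normal")
  # uncovered window: excluded
  expect_true(is.na(classify_boundary(t, z2, tau = 10)))
  # monotone in Zc: raising the threshold never turns defective into normal
  set.seed(23)
  zr <- runif(length(t), 0.5, 1)
  for (tau in c(30, 50, 70)) {
    lab_lo <- classify_boundary(t, zr, tau, Zc = 0.6)
    lab_hi <- classify_boundary(t, zr, tau, Zc = 0.9)
    expect_false(lab_lo == "defective" && lab_hi == "normal")
  }
})

test_that("boundary numbering: chaining and time-based inference", {
  # tau/Ta = 8.75 with Delta = 0.3: round to 9
  expect_equal(number_boundary(8.75 * 30, "normal"), 9L)
  # tau/Ta = 8.65: 9 - 8.65 = 0.35 >= 0.3, assign 8
  expect_equal(number_boundary(8.65 * 30, "normal"), 8L)
  # chaining after a normal boundary wins over the time-based rule
  num <- number_boundary(c(330, 350), c("normal", "normal"))
  expect_equal(num, c(11L, 12L))
  # a defective event breaks the chain
  num2 <- number_boundary(c(330, 350, 382), c("normal", "defective", "normal"))
  expect_equal(num2, c(11L, NA, 13L))
  # collisions keep the earlier event (chain broken by a defective event,
  # then the time-based rule re-derives an already-used number)
  expect_warning(
    num3 <- number_boundary(c(330, 332, 333),
                            c("normal", "defective", "normal"), Ta = 30),
    "already assigned")
  expect_equal(num3, c(11L, NA, NA))
})

test_that("record scoring: ALD, FRS, PLD in both conventions", {
  lab <- rep("normal", 20)
  lab[c(1:9, 11, 14)] <- "defective"
  r <- score_record(lab)
  expect_equal(attr(r, "ALD"), 1L)
  expect_equal(attr(r, "FRS"), 9L)  # jf = 10
  expect_equal(attr(r, "PLD"), 14L) # jp = 15
  # all normal
  r2 <- score_record(rep("normal", 10))
  expect_true(is.na(attr(r2, "ALD")) && is.na(attr(r2, "PLD")))
  expect_equal(attr(r2, "FRS"), 0L)
  # isolated defect block
  lab3 <- rep("normal", 10); lab3[5:7] <- "defective"
  r3 <- score_record(lab3)
  expect_equal(attr(r3, "ALD"), 5L)
  expect_equal(attr(r3, "FRS"), 0L)
  expect_equal(attr(r3, "PLD"), 7L)
  # experimental convention: first normal after segment 9
  lab4 <- rep("defective", 15); lab4[c(3, 12, 13, 14, 15)] <- "normal"
  r4 <- score_record(lab4, convention = "experiment")
  expect_equal(attr(r4, "FRS"), 11L)
  expect_equal(score_record(lab4)$label, r4$label) # labels unchanged
  expect_equal(attr(score_record(lab4), "FRS"), 2L)
  # PLD >= ALD whenever both defined; in records that start defective (the
  # resynchronization situation) FRS >= ALD - 1 in the simulation convention
  set.seed(24)
  for (i in 1:50) {
    lab5 <- c("defective", sample(c("normal", "defective"), 19, replace = TRUE))
    r5 <- score_record(lab5)
    if (!is.na(attr(r5, "ALD")) && !is.na(attr(r5, "PLD")))
      expect_gte(attr(r5, "PLD"), attr(r5, "ALD"))
    if (!is.na(attr(r5, "FRS")) && !is.na(attr(r5, "ALD")))
      expect_gte(attr(r5, "FRS"), attr(r5, "ALD") - 1L)
  }
})

test_that("defect runs between FRS and PLD", {
  # N D D N D N pattern between FRS and PLD
  lab <- c("defective", "normal", "defective", "defective", "normal",
           "defective", "normal")
  expect_equal(sort(defect_runs(score_record(lab))), c(1L, 2L))
  expect_length(defect_runs(score_record(rep("normal", 8))), 0)
  lab2 <- c("normal", rep("defective", 4), "normal")
  expect_equal(defect_runs(score_record(lab2)), 4L)
})

test_that("single/double defect statistics and the independence closed form", {
  mk <- function(def, n = 20) {
    lab <- rep("normal", n); lab[def] <- "defective"; score_record(lab)
  }
  s <- single_double_stats(mk(c(10, 12)), mk(12))
  expect_equal(s$Nt, 2); expect_equal(s$Ns, 1); expect_equal(s$Fs, 0.5)
  # identical sides: all double
  expect_equal(single_double_stats(mk(c(11, 13)), mk(c(11, 13)))$Fs, 0)
  # disjoint defects: all single
  expect_equal(single_double_stats(mk(c(10, 12)), mk(c(11, 13)))$Fs, 1)
  # loci at or before start_after are ignored
  expect_equal(single_double_stats(mk(c(3, 9)), mk(8))$Nt, 0)
  # closed form anchors
  expect_equal(expected_single_fraction(1), 0)
  expect_equal(expected_single_fraction(0), 1)
  expect_equal(expected_single_fraction(0.5), 2 / 3)
})

test_that("Fs of independent Bernoulli sides matches 2(1-p)/(2-p)", {
  # Monte-Carlo oracle at p = 0.5, n = 1e6: agreement < 0.005
  rec <- make_toy_record(1e6, 0.5, 0.5, seed = 99)
  s <- single_double_stats(rec$left, rec$right, start_after = 0)
  expect_lt(abs(s$Fs - 2 / 3), 0.005)
})

test_that("vorticity constants and correlation of a perfect linear ramp", {
  expect_equal(vorticity_constants()$index_var, 35 / 12)
  expect_equal(mean(((0:5) - 5 / 2)^2), 35 / 12)
  # internal correlation: exact 1 for a linear ramp
  expect_equal(psmclock:::.sector_index_corr(seq(0.3, 5.8, length.out = 6)), 1,
               tolerance = 1e-12)
})

test_that("vorticity detector: planted vortex found, gradients and uniform rejected", {
  f_v <- make_planted_field("vortex", box = c(110, 110, 55), seed = 31)
  params <- vorticity_params()
  # core detection in the z = [0, 20] slab at the planted center (55, 55)
  sl <- f_v[f_v$z <= 20, ]
  psi <- vorticity_at_grid(sl$x, sl$y, sl$theta, 55, 55, params, "ccw")
  expect_gte(psi, params$psi_min)
  # the mirrored field swaps handedness channels
  sl_m <- sl; sl_m$y <- 110 - sl_m$y
  psi_m_cw <- vorticity_at_grid(sl_m$x, sl_m$y, sl_m$theta, 55, 55, params, "cw")
  psi_m_ccw <- vorticity_at_grid(sl_m$x, sl_m$y, sl_m$theta, 55, 55, params, "ccw")
  expect_gte(psi_m_cw, params$psi_min)
  expect_equal(psi_m_ccw, 0)
  # uniform field: no vortex anywhere
  f_u <- make_planted_field("uniform", box = c(110, 110, 55), seed = 32)
  pu <- vorticity_profile_box(f_u, c(110, 110, 55), params)
  expect_true(all(pu$psi_cw == 0 & pu$psi_ccw == 0))
  # pure axial gradient: the critical false-positive control
  f_g <- make_planted_field("gradient", box = c(110, 110, 55), seed = 33)
  pg <- vorticity_profile_box(f_g, c(110, 110, 55), params)
  expect_true(all(pg$psi_cw == 0 & pg$psi_ccw == 0))
  # profile peaks at the planted axial center
  pv <- vorticity_profile_box(f_v, c(110, 110, 55), params)
  peak <- pv$x[which.max(pmax(pv$psi_cw, pv$psi_ccw))]
  expect_lt(abs(peak - 55), 10)
  expect_true(all(pv$psi_cw >= 0 & pv$psi_cw <= 1))
})

test_that("planted winding number is +/-1 by the line-integral oracle", {
  for (hand in c("ccw", "cw")) {
    f <- make_planted_field("vortex", handedness = hand, seed = 34,
                            density = 0.004)
    # brute-force line integral: accumulate wrapped phase differences of the
    # nearest cells along a dense circular path around the core
    ang <- seq(0, 2 * pi, length.out = 721)[-721]
    probe_theta <- vapply(ang, function(a) {
      px <- 55 + 12 * cos(a); py <- 55 + 12 * sin(a)
      i <- which.min((f$x - px)^2 + (f$y - py)^2)
      f$theta[i]
    }, numeric(1))
    d <- diff(c(probe_theta, probe_theta[1]))
    d <- (d + pi) %% (2 * pi) - pi
    w <- sum(d) / (2 * pi)
    expect_equal(w, if (hand == "ccw") 1 else -1, tolerance = 1e-9)
  }
})
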