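# Mechanics: advection field, strain rate, motility gradient, polarity
# random walk, pair forces and the neighbor-list assembly.

mech <- mechanics_params()
geom <- geometry_params()

test_that("advection field satisfies its boundary and continuity conditions", {
  L <- 300
  # chi = 0: anterior cells advect at speed va
  v <- advection_velocity(0, xa = 0, L = L, params = mech)
  expect_equal(v[1], -mech$va)
  expect_equal(v[2:3], c(0, 0))
  # chi = 1: the posterior tip is at rest in the tailbud frame
  expect_equal(advection_velocity(L, 0, L, mech)[1], 0)
  # continuity at the knot for random parameter draws
  set.seed(1)
  for (i in 1:25) {
    p <- mechanics_params(va = runif(1, 0.5, 3), xq = runif(1, 0.1, 0.9),
                          vp_early = runif(1, 0, 3), vp_late = runif(1, 0, 3))
    for (t in c(0, 1e6)) {
      below <- advection_velocity(p$xq * L - 1e-9, 0, L, p, t)[1]
      at <- advection_velocity(p$xq * L, 0, L, p, t)[1]
      expect_equal(below, at, tolerance = 1e-6)
      expect_equal(advection_velocity(0, 0, L, p, t)[1], -p$va)
      expect_equal(advection_velocity(L, 0, L, p, t)[1], 0, tolerance = 1e-12)
    }
  }
})

test_that("strain rate is piecewise constant and integrates to va", {
  L <- 300
  p <- mechanics_params(va = 2, vp_early = 0.5, vp_late = 0.5, tg = 0, xq = 0.4)
  expect_equal(strain_rate(0.9, L, p), 0.5 / L)
  expect_equal(strain_rate(0.1, L, p), (2 - 0.5 * 0.6) / (0.4 * L))
  # vp = 0: all deformation anterior
  p0 <- mechanics_params(va = 2, vp_early = 0, vp_late = 0, tg = 0)
  expect_equal(strain_rate(0.8, L, p0), 0)
  # uniform field when va = vp
  pu <- mechanics_params(va = 1.5, vp_early = 1.5, vp_late = 1.5, tg = 0)
  expect_equal(strain_rate(0.2, L, pu), strain_rate(0.8, L, pu))
  # integral of |dv/dx| over the PSM equals the total velocity drop va
  chi <- seq(0, 1, length.out = 20001)
  integ <- mean(strain_rate(chi, L, p)) * L
  expect_equal(integ, p$va, tolerance = 1e-3)
})

test_that("motility gradient is posterior-high with the stated anchors", {
  L <- 300
  expect_equal(motility_speed(L, 0, L, mech), mech$vs)
  p1 <- mechanics_params(Xv = 1)
  expect_equal(motility_speed(0, 0, L, p1), p1$vs / 2)
  # monotone toward the posterior for random shapes
  set.seed(2)
  for (i in 1:20) {
    p <- mechanics_params(Xv = runif(1, 0.1, 2), h = runif(1, 0.5, 6))
    v <- motility_speed(seq(0, L, length.out = 50), 0, L, p)
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("polarity step conserves the norm and is identity without noise", {
  n <- c(0.6, 0.48, 0.64)
  n <- n / sqrt(sum(n^2))
  expect_equal(polarity_step(n, dt = 0.01, Dphi = 0, xi = c(1.2, -0.7)), n)
  set.seed(3)
  for (i in 1:200) {
    out <- polarity_step(n, dt = 0.01, Dphi = 0.5, xi = rnorm(2))
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    n <- out
  }
})

test_that("polarity random walk equilibrates to the uniform law on the sphere", {
  # evolve many independent polarities from a common point; cos(polar angle)
  # must become Uniform[-1, 1] (Kolmogorov-Smirnov)
  set.seed(4)
  nrep <- 2500
  m <- matrix(rep(c(0, 0, 1), each = nrep), nrep, 3)
  dt <- 0.05
  Dphi <- 0.5
  for (s in 1:100) {
    xi <- matrix(rnorm(2 * nrep), nrep, 2)
    for (i in seq_len(nrep))
      m[i, ] <- polarity_step(m[i, ], dt, Dphi, xi[i, ])
  }
  ks <- suppressWarnings(stats::ks.test(m[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # azimuth must be uniform too
  ks2 <- suppressWarnings(stats::ks.test(atan2(m[, 2], m[, 1]), "punif", -pi, pi))
  expect_gt(ks2$p.value, 0.01)
})

test_that("pair force is a cutoff linear repulsion with action-reaction", {
  expect_equal(pair_force(c(0, 0, 0), c(11, 0, 0)), rep(0, 3)) # d = dc
  f <- pair_force(c(0, 0, 0), c(5.5, 0, 0), mu = 8.71, dc = 11)
  expect_equal(f[1], -4.355)                                   # repulsive, away from j
  expect_equal(f[2:3], c(0, 0))
  # Newton's third law over random pairs
  set.seed(5)
  for (i in 1:1000) {
    xi <- runif(3, 0, 20); xj <- runif(3, 0, 20)
    expect_equal(pair_force(xi, xj), -pair_force(xj, xi))
  }
  # coincident cells: finite, equal-and-opposite push
  f0 <- pair_force(c(1, 1, 1), c(1, 1, 1), ids = c(3L, 9L))
  expect_equal(sqrt(sum(f0^2)), 8.71, tolerance = 1e-9)
})

test_that("neighbor-list velocity assembly matches the all-pairs oracle", {
  set.seed(6)
  pos <- sample_domain_points(200, geom, margin = 1, seed = 6)
  phi <- acos(runif(200, -1, 1)); psi <- runif(200, 0, 2 * pi)
  pol <- cbind(sin(phi) * cos(psi), sin(phi) * sin(psi), cos(phi))
  v_grid <- net_velocities(pos, pol, geom, mech, method = "grid")
  v_all <- net_velocities(pos, pol, geom, mech, method = "allpairs")
  expect_lt(max(abs(v_grid - v_all)), 1e-12)
})

test_that("net velocity reduces to its advection term for an isolated cell", {
  p0 <- mechanics_params(vs = 0)
  pos <- matrix(c(150, geom$Yc - geom$R, geom$Zc), 1) # on the left tube axis
  pol <- matrix(c(0, 0, 1), 1)
  v <- net_velocities(pos, pol, geom, p0)
  expect_equal(v[1, 1], advection_velocity(150, 0, geom$Lx, p0)[1],
               tolerance = 1e-9)
  expect_equal(abs(v[1, 2]) + abs(v[1, 3]), 0, tolerance = 1e-9)
  # two overlapping cells near the tailbud tip (wall force off to isolate
  # the pair term): equal and opposite repulsion, identical advection
  p1 <- mechanics_params(vs = 0, mub = 0)
  tip <- c(geom$Lx - 6, geom$Yc, geom$Zc)
  pos2 <- rbind(tip, tip + c(0, 3, 0))
  v2 <- net_velocities(pos2, rbind(pol, pol), geom, p1)
  expect_equal(v2[1, 2], -v2[2, 2], tolerance = 1e-9)
  expect_equal(v2[1, 1], v2[2, 1], tolerance = 1e-9)
})

test_that("momentum-free repulsion: pair forces sum to zero over the tissue", {
  set.seed(7)
  pos <- sample_domain_points(300, geom, margin = 1, seed = 8)
  pol <- matrix(0, 300, 3); pol[, 3] <- 1
  p <- mechanics_params(vs = 0, va = 0, vp_early = 0, vp_late = 0, mub = 0)
  v <- net_velocities(pos, pol, geom, p)
  expect_lt(max(abs(colSums(v))), 1e-9)
})
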