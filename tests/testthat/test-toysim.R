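test_that("Brownian steps are deterministic drift at kT = 0", {
  sys <- toy_system(atom_set(c(0, 0, 0)), kT = 0, gamma = 2, dt = 0.01)
  pos <- sys$atoms$positions
  expect_identical(brownian_step(sys, pos, matrix(0, 1, 3)), pos)
  f <- matrix(c(4, -2, 1), 1, 3)
  stepped <- brownian_step(sys, pos, f)
  expect_equal(stepped, pos + (0.01 / 2) * f)
  expect_error(brownian_step(sys, pos, matrix(NaN, 1, 3)), "non-finite")
})

test_that("free diffusion reproduces the Einstein relation", {
  kT <- 0.7; gamma <- 1.3; dt <- 0.01; n_steps <- 1000; n_rep <- 1000
  sys <- toy_system(atom_set(matrix(0, n_rep, 3)), kT = kT,
                    gamma = gamma, dt = dt)
  set.seed(61)
  pos <- sys$atoms$positions
  zero <- matrix(0, n_rep, 3)
  for (s in seq_len(n_steps)) pos <- brownian_step(sys, pos, zero)
  msd <- mean(pos^2)               # per coordinate
  expected <- 2 * (kT / gamma) * n_steps * dt
  expect_equal(msd, expected, tolerance = 0.1)
})

test_that("unbiased sampling of a harmonic bond reproduces the analytic length variance", {
  # one bond of stiffness kb: 3D relative coordinate is Gaussian with
  # variance kT/kb per component; r-variance follows the chi(3) law
  kb <- 25; kT <- 0.5; r0 <- 3
  sys <- toy_system(
    atom_set(rbind(c(0, 0, 0), c(r0, 0, 0))),
    bonds = data.frame(i = 1, j = 2, k_bond = kb, r0 = r0),
    kT = kT, gamma = 1, dt = 2e-3)
  set.seed(62)
  pos <- sys$atoms$positions
  nsamp <- 0; ssum <- 0; s2sum <- 0
  for (s in 1:100000) {
    pos <- brownian_step(sys, pos, bonded_energy_forces(sys, pos)$forces)
    if (s > 2000 && s %% 10 == 0) {
      r <- sqrt(sum((pos[2, ] - pos[1, ])^2))
      nsamp <- nsamp + 1; ssum <- ssum + r; s2sum <- s2sum + r^2
    }
  }
  var_r <- s2sum / nsamp - (ssum / nsamp)^2
  # for r0 >> sqrt(kT/kb) the bond-length marginal is Gaussian with
  # variance kT/kb (plus O((kT/kb)/r0^2) curvature corrections)
  expect_equal(var_r, kT / kb, tolerance = 0.05 * 3)
})

test_that("bonded forces are the exact negative gradient of the bonded energy", {
  helix <- make_bead_helix(n_beads = 8)
  set.seed(63)
  pos <- helix$atoms$positions + matrix(rnorm(24, 0, 0.3), 8, 3)
  be <- bonded_energy_forces(helix, pos)
  h <- 1e-6
  fd <- matrix(0, 8, 3)
  for (i in 1:8) {
    for (ax in 1:3) {
      pp <- pos; pp[i, ax] <- pp[i, ax] + h
      pm <- pos; pm[i, ax] <- pm[i, ax] - h
      fd[i, ax] <- -(bonded_energy_forces(helix, pp)$U -
                       bonded_energy_forces(helix, pm)$U) / (2 * h)
    }
  }
  expect_lt(rel_err(be$forces, fd), 1e-6)
})

test_that("bead helices are built at their bonded-energy minimum", {
  helix <- make_bead_helix(n_beads = 12, rise = 1.5, radius = 2.3,
                           twist = 100)
  pos <- helix$atoms$positions
  d <- sqrt(rowSums((pos[-1, ] - pos[-12, ])^2))
  expect_lt(diff(range(d)), 1e-9)           # equal bond lengths
  expect_equal(d, helix$bonds$r0, tolerance = 1e-12)
  be <- bonded_energy_forces(helix)
  expect_lt(max(abs(be$forces)), 1e-9)
  expect_lt(be$U, 1e-18)
  expect_error(make_bead_helix(n_beads = 3), "at least 4")
  expect_error(make_bead_helix(radius = 0), "degenerate")
})

test_that("a zero-degree kink target equals the straight-helix spread", {
  helix <- make_bead_helix()
  kt0 <- make_kinked_target(helix, kink_angle = 0)
  straight <- spread_density(helix$atoms,
                             make_geom(dim(kt0$target$values),
                                       origin = kt0$target$origin,
                                       spacing = kt0$target$spacing),
                             kt0$params)
  expect_equal(kt0$target$values, straight$values, tolerance = 1e-14)
  expect_equal(kt0$reference$positions, helix$atoms$positions)
})

test_that("kinking preserves bond lengths and bends by the requested angle", {
  helix <- make_bead_helix()
  kt <- make_kinked_target(helix, kink_angle = 30)
  d0 <- sqrt(rowSums(diff(helix$atoms$positions)^2))
  d1 <- sqrt(rowSums(diff(kt$reference$positions)^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_gt(rmsd_no_superposition(helix$atoms, kt$reference), 1)
})

test_that("identical seeds reproduce refinement trajectories bit for bit", {
  geom <- density_grid(array(0, c(41, 1, 1)), origin = c(-5, 0, 0),
                       spacing = 0.25)
  params <- spread_params(0.8)
  target <- spread_density(atom_set(c(0, 0, 0)), geom, params)
  sys1 <- toy_system(atom_set(c(2, 0, 0)), kT = 0.05, dt = 1e-3)
  sc <- scaling_config(alpha = 0.02, ema_weight = 0.1, k_init = 0.01,
                       f_max = 100)
  t1 <- run_refinement(sys1, target, "re", sc, 2000, seed = 7,
                       params = params)
  t2 <- run_refinement(sys1, target, "re", sc, 2000, seed = 7,
                       params = params)
  expect_identical(t1$log, t2$log)
  expect_identical(t1$final_positions, t2$final_positions)
})

test_that("zero initial force constant with zero alpha gives unbiased dynamics", {
  geom <- density_grid(array(0, c(41, 1, 1)), origin = c(-5, 0, 0),
                       spacing = 0.25)
  params <- spread_params(0.8)
  target <- spread_density(atom_set(c(0, 0, 0)), geom, params)
  sys1 <- toy_system(atom_set(c(2, 0, 0)), kT = 0.05, dt = 1e-3)
  null_sc <- scaling_config(alpha = 0, ema_weight = 0.1, k_init = 0,
                            f_max = Inf)
  tr <- run_refinement(sys1, target, "re", null_sc, 1000, seed = 9,
                       params = params)
  expect_true(all(tr$log$k == 0))
  expect_true(all(tr$log$U_fit == 0))
  # the same seed without any fitting force gives the same path
  set.seed(9)
  pos <- sys1$atoms$positions
  for (s in 1:1000) pos <- brownian_step(sys1, pos, matrix(0, 1, 3))
  expect_equal(tr$final_positions, pos, tolerance = 1e-12)
})

test_that("relative entropy pulls a distant particle in; inner product does not", {
  # long-range vs short-range contrast: the particle starts 5 sigma from
  # the target center, outside the inner-product interaction range but
  # inside the relative-entropy one
  sigma <- 1
  geom <- density_grid(array(0, c(161, 1, 1)), origin = c(-20, 0, 0),
                       spacing = 0.25)
  params <- spread_params(sigma)
  target <- spread_density(atom_set(c(0, 0, 0)), geom, params)
  sys1 <- toy_system(atom_set(c(5 * sigma, 0, 0)), kT = 0.01, gamma = 1,
                     dt = 2e-3)
  sc <- scaling_config(alpha = 0.02, ema_weight = 0.1, k_init = 1e-3,
                       f_max = 50)
  tr <- run_refinement(sys1, target, "re", sc, 30000, seed = 3,
                       params = params, n_fit = 10)
  expect_lt(abs(tr$final_positions[1, 1]), 0.1 * sigma)
  # inner product with a small fixed k: essentially no force arrives
  # beyond the truncation radius, the particle stays far away
  fixed_sc <- scaling_config(alpha = 0, ema_weight = 0.1, k_init = 0.05,
                             f_max = Inf)
  sys2 <- toy_system(atom_set(c(6 * sigma, 0, 0)), kT = 0.01, gamma = 1,
                     dt = 2e-3)
  tr2 <- run_refinement(sys2, target, "ip", fixed_sc, 10000, seed = 3,
                        params = params, n_fit = 10)
  expect_gt(tr2$final_positions[1, 1], 4 * sigma)
})

test_that("landscape scans refuse more than two particles", {
  geom <- density_grid(array(0, c(21, 1, 1)), origin = c(-5, 0, 0),
                       spacing = 0.5)
  target <- spread_density(atom_set(c(0, 0, 0)), geom, spread_params(1))
  sys3 <- toy_system(atom_set(matrix(0, 3, 3)))
  expect_error(landscape_scan(sys3, target, "re", seq(-1, 1, 0.5),
                              spread_params(1)), "1 or 2")
})
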