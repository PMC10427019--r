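test_that("width-selection rules invert the FWHM and EMAN2 conventions", {
  expect_equal(sigma_from_resolution(2 * sqrt(2 * log(2))), 1)
  expect_equal(sigma_from_resolution(2.3548), 1, tolerance = 1e-4)
  # homogeneity and voxel-rule consistency
  expect_equal(sigma_from_resolution(2 * 1.7),
               2 * sigma_from_resolution(1.7))
  expect_identical(sigma_from_voxel(1.23), sigma_from_resolution(2.46))
  expect_equal(sigma_from_voxel(1.17741), 1, tolerance = 1e-5)
  expect_error(sigma_from_resolution(0), "positive")
  expect_error(sigma_from_voxel(-1), "positive")
})

test_that("a unit-amplitude atom on a voxel center spreads to (2 pi)^(-3/2) there", {
  geom <- make_geom(c(17, 17, 17), origin = c(-8, -8, -8))
  m <- spread_density(atom_set(c(0, 0, 0)), geom, spread_params(1))
  expect_equal(m$values[9, 9, 9], (2 * pi)^(-3 / 2), tolerance = 1e-12)
})

test_that("truncation keeps more than 99.8% of the Gaussian mass at 4 sigma", {
  # analytic route: radial chi(3) mass inside radius 4 sigma
  expect_gt(truncation_mass_fraction(4), 0.998)
  # numeric route: fine-grid summation of a truncated spread atom
  geom <- make_geom(c(91, 91, 91), origin = c(-4.5, -4.5, -4.5),
                    spacing = 0.1)
  m <- spread_density(atom_set(c(0, 0, 0)), geom, spread_params(1))
  captured <- sum(m$values) * 0.1^3
  expect_gt(captured, 0.998)
  expect_equal(captured, truncation_mass_fraction(4), tolerance = 1e-3)
  # monotone in the cutoff
  fr <- truncation_mass_fraction(c(1, 2, 3, 4, 5))
  expect_true(all(diff(fr) > 0))
})

test_that("two well-separated atoms carry total mass 2 on a fine grid", {
  geom <- make_geom(c(120, 60, 60), origin = c(-15, -7.5, -7.5),
                    spacing = 0.25)
  atoms <- atom_set(rbind(c(-7, 0, 0), c(7, 0, 0)))
  m <- spread_density(atoms, geom, spread_params(1))
  expect_equal(sum(m$values) * 0.25^3, 2, tolerance = 0.01)
})

test_that("zero atoms and zero amplitudes give an all-zero grid, also when normalizing", {
  geom <- make_geom(c(8, 8, 8))
  empty <- spread_density(atom_set(matrix(numeric(0), 0, 3)), geom,
                          spread_params(1, normalize = TRUE))
  expect_true(all(empty$values == 0))
  hydro <- spread_density(atom_set(c(4, 4, 4), amplitudes = 0), geom,
                          spread_params(1, normalize = TRUE))
  expect_true(all(hydro$values == 0))
})

test_that("normalized spreading sums to one", {
  geom <- make_geom(c(12, 12, 12))
  set.seed(21)
  atoms <- atom_set(matrix(runif(9, 3, 8), 3, 3))
  m <- spread_density(atoms, geom, spread_params(1.2, normalize = TRUE))
  expect_equal(sum(m$values), 1, tolerance = 1e-12)
})

test_that("spreading is translation equivariant", {
  set.seed(22)
  atoms <- atom_set(matrix(runif(12, 2, 6), 4, 3))
  shift <- c(1.7, -2.3, 0.9)
  g1 <- make_geom(c(9, 9, 9), origin = c(0, 0, 0))
  g2 <- make_geom(c(9, 9, 9), origin = shift)
  moved <- atoms
  moved$positions <- sweep(atoms$positions, 2, shift, `+`)
  p <- spread_params(1.1)
  expect_equal(spread_density(moved, g2, p)$values,
               spread_density(atoms, g1, p)$values, tolerance = 1e-12)
})

test_that("anisotropic spacing is rejected and undersampling warns", {
  geom <- density_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
  expect_error(spread_density(atom_set(c(1, 1, 1)), geom,
                              spread_params(1)), "anisotropic")
  iso <- make_geom(c(6, 6, 6))
  expect_warning(spread_density(atom_set(c(3, 3, 3)), iso,
                                spread_params(0.3)), "undersampled")
})

test_that("spread_gradient matches finite differences of the weighted spread", {
  set.seed(23)
  geom <- make_geom(c(8, 8, 8))
  atoms <- atom_set(matrix(runif(15, 1.5, 5.5), 5, 3))
  params <- covering_params(geom, 1.2)
  w <- array(rnorm(512), c(8, 8, 8))
  gr <- spread_gradient(atoms, geom, params, w)
  h <- 1e-6
  fd <- matrix(0, 5, 3)
  obj <- function(a) sum(w * spread_density(a, geom, params)$values)
  for (i in 1:5) {
    for (ax in 1:3) {
      ap <- atoms; ap$positions[i, ax] <- ap$positions[i, ax] + h
      am <- atoms; am$positions[i, ax] <- am$positions[i, ax] - h
      fd[i, ax] <- (obj(ap) - obj(am)) / (2 * h)
    }
  }
  expect_lt(rel_err(gr, fd), 1e-5)
})

test_that("symmetric weights about an on-center atom give zero gradient, zero weights give zero", {
  geom <- make_geom(c(9, 9, 9), origin = c(-4, -4, -4))
  atoms <- atom_set(c(0, 0, 0))
  params <- spread_params(1)
  sym_w <- spread_density(atoms, geom, params)$values  # symmetric field
  g <- spread_gradient(atoms, geom, params, sym_w)
  expect_equal(g, matrix(0, 1, 3), tolerance = 1e-12)
  g0 <- spread_gradient(atoms, geom, params, array(0, c(9, 9, 9)))
  expect_identical(g0, matrix(0, 1, 3))
  expect_error(spread_gradient(atoms, geom, params, array(0, c(2, 2, 2))),
               "shape")
})

test_that("degenerate grids use the active-dimension normalization (1D mass is 1)", {
  geom <- density_grid(array(0, c(161, 1, 1)), origin = c(-8, 0, 0),
                       spacing = 0.1)
  m <- spread_density(atom_set(c(0, 0, 0)), geom, spread_params(1))
  # 1D Gaussian mass within 4 sigma
  expect_equal(sum(m$values) * 0.1, 2 * pnorm(4) - 1, tolerance = 1e-3)
  expect_equal(max(m$values), 1 / sqrt(2 * pi), tolerance = 1e-12)
})
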