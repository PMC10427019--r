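# Shared fixtures and independent oracles used across the test files.

# A geometry-only grid (values all zero).
make_geom <- function(dims, origin = c(0, 0, 0), spacing = 1) {
  density_grid(array(0, dims), origin = origin, spacing = spacing)
}

# Random strictly positive density on a small grid.
random_positive_grid <- function(dims, spacing = 1, lo = 0.2, hi = 1.2) {
  density_grid(array(stats::runif(prod(dims), lo, hi), dims),
               spacing = spacing)
}

# Spreading parameters whose truncation sphere covers an entire grid from
# any atom position inside it, so U_fit is smooth for finite-difference
# checks (the hard cutoff makes it only piecewise-smooth otherwise).
covering_params <- function(grid, sigma, normalize = FALSE) {
  ext <- sqrt(sum((dim(grid$values) * grid$spacing)^2))
  spread_params(sigma, cutoff_multiple = 2 * ext / sigma,
                normalize = normalize)
}

# Central finite differences of -U_fit over atom coordinates.
fd_fitting_forces <- function(ff, atoms, h = 1e-6) {
  fd <- matrix(0, n_atoms(atoms), 3)
  for (i in seq_len(n_atoms(atoms))) {
    for (ax in 1:3) {
      ap <- atoms; ap$positions[i, ax] <- ap$positions[i, ax] + h
      am <- atoms; am$positions[i, ax] <- am$positions[i, ax] - h
      fd[i, ax] <- -(fitting_forces(ff, ap)$U_fit -
                       fitting_forces(ff, am)$U_fit) / (2 * h)
    }
  }
  fd
}

rel_err <- function(a, b) {
  norm(a - b, "F") / max(norm(b, "F"), .Machine$double.eps)
}

# Kabsch superposition oracle: optimal-rotation RMSD after centering.
kabsch_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(t(ac) %*% bc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- ac %*% t(R)
  sqrt(mean(rowSums((rot - bc)^2)))
}
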