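# Map-map and model-model agreement metrics: Fourier shell correlation
# (FSC), its unweighted average, threshold resolution, and
# superposition-free RMSD.

# Per-axis frequency indices (in cycles per box) for an FFT of length n.
.freq_index <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k <= n %/% 2, k, k - n)
}

#' Fourier shell correlation between two maps
#'
#' `FSC(s) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)` over
#' radial shells of one reciprocal-voxel width, from the first shell up
#' to Nyquist (the DC term is excluded).  Both maps must share shape and
#' spacing; degenerate (size-1) dimensions are handled so 1D/2D grids
#' work too.
#'
#' @param map1,map2 [density_grid()]s on the same grid.
#' @return An object of class `fsc_curve`: data frame with columns
#'   `shell` (index), `freq` (spatial frequency, 1/Angstrom), `fsc`, and
#'   `n_voxels` (Fourier samples per shell).
#' @export
fsc_curve <- function(map1, map2) {
  stopifnot_grid(map1); stopifnot_grid(map2)
  if (!identical(dim(map1$values), dim(map2$values))) {
    stop("map shapes differ: ", paste(dim(map1$values), collapse = "x"),
         " vs ", paste(dim(map2$values), collapse = "x"))
  }
  if (max(abs(map1$spacing - map2$spacing)) > 1e-6 * mean(map1$spacing)) {
    stop("map spacings differ")
  }
  if (all(map1$values == 0) || all(map2$values == 0)) {
    stop("FSC undefined: all-zero map")
  }
  d <- dim(map1$values)
  active <- which(d > 1L)
  if (length(active) == 0) stop("FSC undefined on a single voxel")
  sp <- map1$spacing
  F1 <- stats::fft(map1$values)
  F2 <- stats::fft(map2$values)
  # radial shell index: physical |s| in units of the finest box frequency
  box_freq <- 1 / (d[active] * sp[active])
  du <- min(box_freq)                    # shell width, 1/A
  fx <- .freq_index(d[1]) / (d[1] * sp[1])
  fy <- .freq_index(d[2]) / (d[2] * sp[2])
  fz <- .freq_index(d[3]) / (d[3] * sp[3])
  s2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  shell <- as.integer(round(sqrt(s2) / du))
  nyq <- min(d[active] %/% 2)
  keep <- shell >= 1L & shell <= nyq
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  sh <- shell[keep]
  num_s <- tapply(num[keep], sh, sum)
  p1_s <- tapply(p1[keep], sh, sum)
  p2_s <- tapply(p2[keep], sh, sum)
  cnt <- as.integer(tapply(rep(1L, sum(keep)), sh, sum))
  idx <- as.integer(names(num_s))
  fsc <- as.numeric(num_s) / sqrt(as.numeric(p1_s) * as.numeric(p2_s))
  out <- data.frame(shell = idx, freq = idx * du, fsc = fsc,
                    n_voxels = cnt)
  out <- out[order(out$shell), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Unweighted FSC average
#'
#' The arithmetic mean of the per-shell FSC values, with no weighting by
#' shell voxel counts; a compact convergence monitor for refinement runs.
#'
#' @param curve an `fsc_curve` from [fsc_curve()].
#' @return Scalar average.
#' @export
fsc_average <- function(curve) {
  if (!inherits(curve, "fsc_curve")) stop("expected an 'fsc_curve'")
  if (nrow(curve) == 0) stop("empty FSC curve")
  mean(curve$fsc)
}

#' Resolution at an FSC threshold
#'
#' The reciprocal of the first frequency at which the FSC crosses below
#' the threshold, linearly interpolated between shells.  If the curve
#' never crosses, the Nyquist-limit resolution is returned with
#' `no_crossing = TRUE`.
#'
#' @param curve an `fsc_curve`.
#' @param threshold FSC threshold in (0, 1); 0.143 is the conventional
#'   map-resolution criterion.
#' @return A list with `resolution` (Angstrom), `freq` (1/Angstrom) and
#'   `no_crossing`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  if (!inherits(curve, "fsc_curve")) stop("expected an 'fsc_curve'")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0,1)")
  below <- which(curve$fsc < threshold)
  if (length(below) == 0) {
    f <- max(curve$freq)
    return(list(resolution = 1 / f, freq = f, no_crossing = TRUE))
  }
  b <- below[1]
  if (b == 1L) {
    f <- curve$freq[1]
  } else {
    f0 <- curve$freq[b - 1]; f1 <- curve$freq[b]
    y0 <- curve$fsc[b - 1]; y1 <- curve$fsc[b]
    f <- f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0)
  }
  list(resolution = 1 / f, freq = f, no_crossing = FALSE)
}

#' Gaussian width for the EMAN2 resolution convention
#'
#' `sigma = resolution / (pi sqrt(2))`, the pdb2mrc convention used when
#' generating comparison densities for FSC monitoring (2 Angstrom
#' resolution corresponds to sigma of about 0.45 Angstrom).
#'
#' @param resolution resolution in Angstrom (> 0).
#' @return sigma in Angstrom.
#' @export
sigma_for_eman2_resolution <- function(resolution) {
  if (any(!is.finite(resolution)) || any(resolution <= 0)) {
    stop("'resolution' must be positive")
  }
  resolution / (pi * sqrt(2))
}

#' Blur a map with an analytic Gaussian transfer function
#'
#' Multiplies the map's Fourier coefficients by
#' `exp(-2 pi^2 sigma_b^2 s^2)`, the exact transform of a Gaussian
#' kernel of real-space width `sigma_b`.
#'
#' @param grid a [density_grid()].
#' @param sigma_b blur width in Angstrom (>= 0).
#' @return The blurred [density_grid()].
#' @export
blur_map <- function(grid, sigma_b) {
  stopifnot_grid(grid)
  if (sigma_b < 0) stop("'sigma_b' must be >= 0")
  if (sigma_b == 0) return(grid)
  d <- dim(grid$values)
  fx <- .freq_index(d[1]) / (d[1] * grid$spacing[1])
  fy <- .freq_index(d[2]) / (d[2] * grid$spacing[2])
  fz <- .freq_index(d[3]) / (d[3] * grid$spacing[3])
  s2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  att <- exp(-2 * pi^2 * sigma_b^2 * s2)
  v <- Re(stats::fft(stats::fft(grid$values) * att, inverse = TRUE)) /
    length(grid$values)
  density_grid(v, origin = grid$origin, spacing = grid$spacing)
}

#' RMSD without superposition
#'
#' Root-mean-square coordinate deviation in the absolute frame, with no
#' rotational or translational alignment: the density map provides the
#' frame of reference, so refined and reference models are compared in
#' place.  This is an upper bound on the aligned RMSD.  Atoms with zero
#' amplitude (hydrogens) are excluded.
#'
#' @param atoms_a,atoms_b [atom_set()]s with equal atom counts in
#'   matched order.
#' @return RMSD in Angstrom.
#' @export
rmsd_no_superposition <- function(atoms_a, atoms_b) {
  if (!inherits(atoms_a, "atom_set") || !inherits(atoms_b, "atom_set")) {
    stop("expected 'atom_set' objects")
  }
  if (n_atoms(atoms_a) != n_atoms(atoms_b)) {
    stop("atom counts differ: ", n_atoms(atoms_a), " vs ",
         n_atoms(atoms_b))
  }
  heavy <- atoms_a$amplitudes > 0 & atoms_b$amplitudes > 0
  if (!any(heavy)) stop("no heavy atoms to compare")
  d <- atoms_a$positions[heavy, , drop = FALSE] -
    atoms_b$positions[heavy, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}
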