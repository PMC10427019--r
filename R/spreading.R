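# Forward model: truncated Gaussian spreading of atoms onto a voxel grid,
# and its analytic coordinate gradient.
#
# Each atom i contributes A_i * (2 pi sigma^2)^(-d/2) *
# exp(-|r_i - c_v|^2 / (2 sigma^2)) to every voxel center c_v within
# cutoff_multiple * sigma; nothing beyond (hard spherical truncation in
# real space).  d is the number of non-degenerate grid dimensions, so the
# same code serves 1D/2D model systems and 3D maps, and each atom's
# untruncated Gaussian integrates to A_i.

#' Spreading parameters for the Gaussian forward model
#'
#' @param sigma Gaussian width sigma in Angstrom (isotropic, > 0).
#' @param cutoff_multiple truncation radius in units of sigma (> 0,
#'   default 4; at 4 sigma more than 99.8% of a 3D Gaussian's mass is
#'   captured).
#' @param normalize if `TRUE`, the spread grid is rescaled so its voxel
#'   values sum to 1 (required by the relative-entropy scores, which
#'   compare probability densities).  A zero-amplitude system stays
#'   all-zero.
#' @return An object of class `spread_params`.
#' @export
spread_params <- function(sigma, cutoff_multiple = 4, normalize = FALSE) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  if (!is.finite(cutoff_multiple) || cutoff_multiple <= 0) {
    stop("'cutoff_multiple' must be positive")
  }
  structure(list(sigma = sigma, cutoff_multiple = cutoff_multiple,
                 normalize = isTRUE(normalize)),
            class = "spread_params")
}

#' Gaussian width from a target resolution
#'
#' Returns the sigma of a Gaussian whose full width at half maximum
#' equals the given resolution: `sigma = resolution / (2 sqrt(2 ln 2))`.
#' This balances information loss from grid under-sampling against loss
#' from over-blurring, and gives a narrower spread than conventions that
#' match the map's nominal resolution.
#'
#' @param resolution target resolution in Angstrom (> 0).
#' @return sigma in Angstrom.
#' @examples
#' sigma_from_resolution(2 * sqrt(2 * log(2)))  # 1 A
#' @export
sigma_from_resolution <- function(resolution) {
  if (any(!is.finite(resolution)) || any(resolution <= 0)) {
    stop("'resolution' must be positive")
  }
  resolution / (2 * sqrt(2 * log(2)))
}

#' Gaussian width from the voxel size
#'
#' The maximum resolution representable on a grid is twice the voxel size
#' (the Nyquist limit), so `sigma_from_voxel(d)` equals
#' `sigma_from_resolution(2 d)`.  Used when no local-resolution estimate
#' is available.
#'
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @return sigma in Angstrom.
#' @examples
#' sigma_from_voxel(1.23)  # about 1.045 A
#' @export
sigma_from_voxel <- function(voxel_size) {
  sigma_from_resolution(2 * voxel_size)
}

# Number of active (non-degenerate) dimensions of a grid geometry.
.active_dims <- function(dims) {
  d <- sum(dims > 1L)
  if (d == 0L) 3L else d
}

.check_spread_geometry <- function(grid, params) {
  stopifnot_grid(grid)
  if (!inherits(params, "spread_params")) {
    stop("expected 'spread_params'")
  }
  dims <- dim(grid$values)
  active <- which(dims > 1L)
  if (length(active) > 1L) {
    sp <- grid$spacing[active]
    if (diff(range(sp)) > 1e-9 * mean(sp)) {
      stop("anisotropic grid spacing is not supported by the spreading ",
           "module (spacings: ", paste(signif(sp, 6), collapse = ", "), ")")
    }
  }
  delta <- grid$spacing[if (length(active)) active[1] else 1L]
  if (params$sigma < delta / 2) {
    warning("sigma = ", signif(params$sigma, 4), " A is smaller than half ",
            "the voxel size (", signif(delta, 4),
            " A): Gaussian is undersampled on this grid")
  }
  invisible(delta)
}

# Shared kernel: loops over atoms, visits the voxel window within the
# truncation sphere, and either accumulates density or contracts the
# analytic gradient with voxel weights.
.spread_core <- function(atoms, grid, params, weights = NULL) {
  dims <- dim(grid$values)
  sigma <- params$sigma
  rad <- params$cutoff_multiple * sigma
  d_active <- .active_dims(dims)
  norm_c <- (2 * pi * sigma^2)^(-d_active / 2)
  ax <- lapply(1:3, function(a) grid_axis_centers(grid, a))
  pos <- atoms$positions
  amps <- atoms$amplitudes
  n <- nrow(pos)
  grad <- if (!is.null(weights)) matrix(0, n, 3) else NULL
  vals <- if (is.null(weights)) array(0, dims) else NULL
  inv2s2 <- 1 / (2 * sigma^2)
  for (i in seq_len(n)) {
    if (amps[i] == 0) next
    lo <- integer(3); hi <- integer(3)
    skip <- FALSE
    for (a in 1:3) {
      lo[a] <- max(1L, ceiling((pos[i, a] - rad - grid$origin[a]) /
                                 grid$spacing[a]) + 1L)
      hi[a] <- min(dims[a], floor((pos[i, a] + rad - grid$origin[a]) /
                                    grid$spacing[a]) + 1L)
      if (lo[a] > hi[a]) { skip <- TRUE; break }
    }
    if (skip) next
    dx <- ax[[1]][lo[1]:hi[1]] - pos[i, 1]
    dy <- ax[[2]][lo[2]:hi[2]] - pos[i, 2]
    dz <- ax[[3]][lo[3]:hi[3]] - pos[i, 3]
    d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    g <- amps[i] * norm_c * exp(-d2 * inv2s2)
    g[d2 > rad^2] <- 0
    if (is.null(weights)) {
      vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] + g
    } else {
      wg <- weights[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] * g
      sx <- rowSums(wg, dims = 1)
      sy <- rowSums(colSums(wg, dims = 1))
      sz <- colSums(wg, dims = 2)
      grad[i, ] <- c(sum(sx * dx), sum(sy * dy), sum(sz * dz)) / sigma^2
    }
  }
  if (is.null(weights)) vals else grad
}

#' Spread atoms onto a grid: the model density
#'
#' Generates the model density by placing a truncated Gaussian of width
#' `sigma` on each atom and evaluating it at voxel centers (point
#' evaluation, no per-voxel integration).  With `normalize = TRUE` the
#' result is rescaled to unit sum, as required by the relative-entropy
#' similarity scores.
#'
#' @param atoms an [atom_set()].
#' @param grid_geometry a [density_grid()] supplying dimensions, origin
#'   and spacing (its values are ignored).
#' @param params a [spread_params()].
#' @return A [density_grid()] with the model density.
#' @seealso [spread_gradient()]
#' @export
spread_density <- function(atoms, grid_geometry, params) {
  if (!inherits(atoms, "atom_set")) stop("expected an 'atom_set' object")
  .check_spread_geometry(grid_geometry, params)
  vals <- .spread_core(atoms, grid_geometry, params)
  if (params$normalize) {
    tot <- sum(vals)
    if (tot > 0) vals <- vals / tot
  }
  density_grid(vals, origin = grid_geometry$origin,
               spacing = grid_geometry$spacing)
}

#' Weighted coordinate gradient of the model density
#'
#' Returns, for each atom i, `sum_v w_v * grad_{r_i} rho^s_v`, using the
#' analytic Gaussian gradient
#' `grad_{r_i} rho^s_v = rho^s_{v,i} (c_v - r_i) / sigma^2`, truncated
#' identically to [spread_density()].  Contracting with the per-voxel
#' derivative of a similarity score yields density-fitting forces.
#'
#' @param atoms an [atom_set()].
#' @param grid_geometry a [density_grid()] defining the grid.
#' @param params a [spread_params()].  The `normalize` flag is ignored
#'   here: gradients are of the raw (unnormalized) spread, and any
#'   normalization Jacobian belongs to the score derivative.
#' @param voxel_weights numeric array (or [density_grid()]) on the same
#'   grid.
#' @return `N x 3` matrix of per-atom gradient vectors.
#' @export
spread_gradient <- function(atoms, grid_geometry, params, voxel_weights) {
  if (!inherits(atoms, "atom_set")) stop("expected an 'atom_set' object")
  .check_spread_geometry(grid_geometry, params)
  w <- if (is_density_grid(voxel_weights)) voxel_weights$values else
    voxel_weights
  if (is.null(dim(w))) w <- array(w, c(length(w), 1L, 1L))
  if (!identical(dim(w), dim(grid_geometry$values))) {
    stop("weight grid shape ", paste(dim(w), collapse = "x"),
         " does not match grid ",
         paste(dim(grid_geometry$values), collapse = "x"))
  }
  .spread_core(atoms, grid_geometry, params, weights = w)
}

#' Analytic mass fraction of a 3D Gaussian inside a truncation sphere
#'
#' The fraction of an isotropic 3D Gaussian's total mass lying within
#' radius `cutoff_multiple * sigma`, i.e. the chi-squared (df = 3) CDF at
#' `cutoff_multiple^2`.  At the default truncation of 4 sigma this
#' exceeds 99.8%.
#'
#' @param cutoff_multiple truncation radius in units of sigma.
#' @return Fraction in (0, 1).
#' @examples
#' truncation_mass_fraction(4)
#' @export
truncation_mass_fraction <- function(cutoff_multiple) {
  if (any(!is.finite(cutoff_multiple)) || any(cutoff_multiple <= 0)) {
    stop("'cutoff_multiple' must be positive")
  }
  stats::pchisq(cutoff_multiple^2, df = 3)
}
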