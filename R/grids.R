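#' Density grid on a regular voxel lattice
#'
#' A `density_grid` holds per-voxel density values on a regular
#' `(nx, ny, nz)` grid together with its geometry: the Cartesian position
#' of the center of voxel `(1,1,1)` (`origin`, in Angstrom) and the voxel
#' edge length per axis (`spacing`, in Angstrom).  One- and two-dimensional
#' model systems use degenerate trailing dimensions of size 1.  The value
#' stored per voxel is the density evaluated at the voxel center, not a
#' voxel integral.
#'
#' @param values numeric vector, matrix or 3D array of voxel values.
#'   Vectors become `(n,1,1)` grids, matrices `(nr,nc,1)` grids.
#' @param origin numeric length-3, position (Angstrom) of the center of the
#'   first voxel.
#' @param spacing voxel edge length (Angstrom); a scalar is recycled to all
#'   three axes.  Must be strictly positive.
#' @return An object of class `density_grid` with elements `values`
#'   (3D array), `origin` and `spacing` (length-3 numerics).
#' @examples
#' g <- density_grid(array(0, c(8, 8, 8)), origin = c(0, 0, 0), spacing = 1)
#' dim(g$values)
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = 1) {
  if (is.null(dim(values))) {
    values <- array(as.numeric(values), c(length(values), 1L, 1L))
  } else if (length(dim(values)) == 2L) {
    values <- array(as.numeric(values), c(dim(values), 1L))
  } else if (length(dim(values)) == 3L) {
    values <- array(as.numeric(values), dim(values))
  } else {
    stop("'values' must have at most 3 dimensions")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || length(origin) != 3L) {
    stop("'origin' and 'spacing' must have length 3")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid spacing must be strictly positive on every axis")
  }
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(!is.finite(values))) stop("grid values must be finite")
  structure(list(values = values, origin = origin, spacing = spacing),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  origin  (A): %.4g %.4g %.4g\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  spacing (A): %.4g %.4g %.4g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range: [%.4g, %.4g], sum %.4g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

is_density_grid <- function(x) inherits(x, "density_grid")

stopifnot_grid <- function(x) {
  if (!is_density_grid(x)) stop("expected a 'density_grid' object")
  invisible(x)
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid a [density_grid()].
#' @param axis axis index (1 = x, 2 = y, 3 = z).
#' @return Numeric vector of voxel-center positions (Angstrom).
#' @export
grid_axis_centers <- function(grid, axis) {
  stopifnot_grid(grid)
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Geometric center of the grid box
#'
#' The box center is the midpoint between the first and last voxel centers.
#'
#' @param grid a [density_grid()].
#' @return Numeric length-3 position (Angstrom).
#' @export
grid_box_center <- function(grid) {
  stopifnot_grid(grid)
  grid$origin + (dim(grid$values) - 1) / 2 * grid$spacing
}

#' Is the grid spacing isotropic?
#' @param grid a [density_grid()].
#' @param tol relative tolerance.
#' @return Logical scalar.
#' @export
grid_is_isotropic <- function(grid, tol = 1e-9) {
  stopifnot_grid(grid)
  diff(range(grid$spacing)) <= tol * mean(grid$spacing)
}

#' Set of particles with spreading amplitudes
#'
#' An `atom_set` stores `N x 3` Cartesian positions (Angstrom) together
#' with per-atom Gaussian spreading amplitudes.  Amplitudes follow the
#' convention that heavy atoms contribute unit mass to the model density
#' and hydrogens contribute nothing (amplitude 0); they must be
#' nonnegative.
#'
#' @param positions numeric `N x 3` matrix (or length-3 vector for a
#'   single atom) of coordinates in Angstrom.
#' @param amplitudes per-atom nonnegative spreading amplitudes; a scalar
#'   is recycled.
#' @param labels optional character vector of atom/element names.
#' @return An object of class `atom_set`.
#' @examples
#' a <- atom_set(rbind(c(0, 0, 0), c(1.5, 0, 0)))
#' n_atoms(a)
#' @export
atom_set <- function(positions, amplitudes = 1, labels = NULL) {
  if (is.null(dim(positions))) {
    if (length(positions) == 0) {
      positions <- matrix(numeric(0), 0L, 3L)
    } else if (length(positions) == 3L) {
      positions <- matrix(as.numeric(positions), 1L, 3L)
    } else {
      stop("'positions' must be an N x 3 matrix")
    }
  }
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L) stop("'positions' must have 3 columns")
  if (any(!is.finite(positions))) stop("atom positions must be finite")
  n <- nrow(positions)
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, n)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != n) stop("one amplitude per atom required")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("amplitudes must be finite and nonnegative")
  }
  if (!is.null(labels) && length(labels) != n) {
    stop("one label per atom required")
  }
  structure(list(positions = positions, amplitudes = amplitudes,
                 labels = labels),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("atom_set: %d atoms (%d with zero amplitude)\n",
              nrow(x$positions), sum(x$amplitudes == 0)))
  invisible(x)
}

#' Number of atoms in an atom set
#' @param atoms an [atom_set()].
#' @return Integer count.
#' @export
n_atoms <- function(atoms) {
  if (!inherits(atoms, "atom_set")) stop("expected an 'atom_set' object")
  nrow(atoms$positions)
}

#' Translate atoms so their center of geometry sits at the grid box center
#'
#' Rigid translation only: the internal geometry (all pairwise distances)
#' is preserved exactly.  Used for the rough initial alignment that places
#' a model in the density box before refinement.
#'
#' @param atoms an [atom_set()] with at least one atom.
#' @param grid a [density_grid()] defining the box.
#' @return A translated copy of `atoms`.
#' @export
center_in_grid <- function(atoms, grid) {
  if (!inherits(atoms, "atom_set")) stop("expected an 'atom_set' object")
  stopifnot_grid(grid)
  if (n_atoms(atoms) == 0) stop("cannot center an empty atom_set")
  cog <- colMeans(atoms$positions)
  shift <- grid_box_center(grid) - cog
  out <- atoms
  out$positions <- sweep(atoms$positions, 2, shift, `+`)
  out
}
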