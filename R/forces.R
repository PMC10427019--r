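# Density-fitting forces: composition of the per-voxel score derivative
# with the spreading gradient,
#   F_i = k * sum_v dS/d rho^s_v * grad_{r_i} rho^s_v,
# evaluated in real space.  Under the implemented conventions
# (U_fit = -k S, normalization Jacobian inside the score derivative) the
# forces are the exact negative coordinate gradient of U_fit.

#' Density-fitting force field
#'
#' Bundles everything needed to evaluate fitting forces: the similarity
#' kind, the prepared target, the spreading parameters, the force
#' constant `k` (energy per score unit) and the multiple-time-stepping
#' period `n_fit`.
#'
#' @param kind similarity kind or short token (see [similarity_kind()]).
#' @param target a raw [density_grid()] or a `prepared_target`; raw grids
#'   are prepared automatically for the given kind.
#' @param params a [spread_params()].
#' @param k force constant, >= 0.
#' @param n_fit integer >= 1; fitting forces are applied every `n_fit`
#'   integration steps, scaled by `n_fit`.
#' @return An object of class `fitting_force_field`.
#' @export
fitting_force_field <- function(kind, target, params, k = 1, n_fit = 1L) {
  kind <- similarity_kind(kind)
  if (is_density_grid(target)) target <- prepare_target(target, kind)
  if (!inherits(target, "prepared_target")) {
    stop("'target' must be a density_grid or prepared_target")
  }
  if (!identical(target$kind, kind)) {
    stop("target was prepared for kind '", target$kind, "'")
  }
  if (!inherits(params, "spread_params")) stop("expected 'spread_params'")
  if (!is.finite(k) || k < 0) stop("'k' must be finite and >= 0")
  if (n_fit < 1) stop("'n_fit' must be >= 1")
  structure(list(kind = kind, target = target, params = params,
                 k = k, n_fit = as.integer(n_fit)),
            class = "fitting_force_field")
}

# Geometry-only grid matching a prepared target.
.target_geometry <- function(target) {
  density_grid(array(0, dim(target$values)), origin = target$origin,
               spacing = target$spacing)
}

#' Fitting forces, similarity and fitting energy for a configuration
#'
#' Evaluates the forward model at the current coordinates, scores it
#' against the target, and assembles per-atom forces
#' `F_i = k * sum_v dS/d rho^s_v * grad_{r_i} rho^s_v`.  The returned
#' energy is `U_fit = -k * S`; forces are its exact negative gradient.
#'
#' @param ff a [fitting_force_field()].
#' @param atoms an [atom_set()].
#' @return A list with `forces` (`N x 3` matrix), `S` (similarity), and
#'   `U_fit` (energy).
#' @export
fitting_forces <- function(ff, atoms) {
  if (!inherits(ff, "fitting_force_field")) {
    stop("expected a 'fitting_force_field'")
  }
  geom <- .target_geometry(ff$target)
  raw_params <- ff$params
  raw_params$normalize <- FALSE
  model <- spread_density(atoms, geom, raw_params)
  sc <- score(ff$kind, ff$target, model)
  if (ff$k == 0) {
    fr <- matrix(0, n_atoms(atoms), 3)
  } else {
    w <- score_derivative(ff$kind, ff$target, model)
    fr <- ff$k * spread_gradient(atoms, geom, raw_params, w)
  }
  list(forces = fr, S = sc$S, U_fit = -ff$k * sc$S)
}

#' Scale fitting forces for multiple time-stepping
#'
#' When density forces are applied only every `n_fit` integration steps,
#' they are multiplied by `n_fit` so that the same total impulse is
#' delivered as if they were applied every step (approximating the same
#' effective Hamiltonian).
#'
#' @param forces `N x 3` force matrix.
#' @param n_fit application period, integer >= 1.
#' @return Scaled force matrix.
#' @export
apply_multiple_timestep <- function(forces, n_fit) {
  if (!is.numeric(n_fit) || length(n_fit) != 1L || n_fit < 1) {
    stop("'n_fit' must be a single number >= 1")
  }
  forces * n_fit
}

#' Advisory maximum time step for the map potential
#'
#' Estimates the stiffest local curvature of `U_fit` by central finite
#' differences of the fitting force over atom coordinates and returns the
#' overdamped Euler stability limit `2 gamma / kappa_max`.  Advisory
#' only: the fastest oscillation depends on the reference density, the
#' similarity kind and the force constant, so it is probed numerically at
#' the given configuration rather than derived.
#'
#' @param ff a [fitting_force_field()].
#' @param atoms an [atom_set()].
#' @param gamma friction coefficient of the intended propagator.
#' @param h displacement (Angstrom) for the curvature probe.
#' @return Estimated maximum stable time step (same time units as
#'   `gamma`); `Inf` if the potential is locally flat.
#' @export
estimate_max_timestep <- function(ff, atoms, gamma = 1, h = 1e-4) {
  kmax <- 0
  for (i in seq_len(n_atoms(atoms))) {
    for (a in 1:3) {
      ap <- atoms; ap$positions[i, a] <- ap$positions[i, a] + h
      am <- atoms; am$positions[i, a] <- am$positions[i, a] - h
      fp <- fitting_forces(ff, ap)$forces[i, a]
      fm <- fitting_forces(ff, am)$forces[i, a]
      kmax <- max(kmax, -(fp - fm) / (2 * h))
    }
  }
  if (kmax <= 0) Inf else 2 * gamma / kmax
}
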