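# Minimal stochastic particle dynamics: overdamped Brownian propagation
# of bead models with harmonic bonds and angles, combined with density
# fitting forces under adaptive force scaling.
#
# The model studies the engine supports (effective 1D/2D landscapes, the
# fixed-vs-adaptive Brownian work benchmark, bead-helix refinement into a
# kinked synthetic density) probe the similarity potentials and the
# scaling protocol; their claims are propagator-agnostic, so the simple
# overdamped integrator x <- x + (dt/gamma) F + sqrt(2 kT dt/gamma) xi
# is used throughout rather than a thermostatted velocity integrator.

#' Toy particle system
#'
#' @param atoms an [atom_set()] with the mobile particles.
#' @param bonds optional data frame / matrix with columns `i`, `j`,
#'   `k_bond` (energy/A^2) and `r0` (A): harmonic bond terms
#'   `0.5 k (r - r0)^2`.
#' @param angles optional data frame / matrix with columns `i`, `j`, `k`,
#'   `k_angle` (energy/rad^2) and `theta0` (rad): harmonic angle terms at
#'   the middle atom `j`.
#' @param kT thermal energy (>= 0; energy units set the unit system).
#' @param gamma friction coefficient (> 0).
#' @param dt integration time step (> 0).
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(atoms, bonds = NULL, angles = NULL, kT = 1,
                       gamma = 1, dt = 1e-3) {
  if (!inherits(atoms, "atom_set")) stop("expected an 'atom_set'")
  n <- n_atoms(atoms)
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "k_bond", "r0") %in% names(bonds)))
    if (any(bonds$i == bonds$j) ||
        any(c(bonds$i, bonds$j) < 1) || any(c(bonds$i, bonds$j) > n)) {
      stop("invalid bond indices")
    }
  }
  if (!is.null(angles)) {
    angles <- as.data.frame(angles)
    stopifnot(all(c("i", "j", "k", "k_angle", "theta0") %in% names(angles)))
    idx <- c(angles$i, angles$j, angles$k)
    if (any(idx < 1) || any(idx > n)) stop("invalid angle indices")
  }
  if (!is.finite(kT) || kT < 0) stop("'kT' must be >= 0")
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be positive")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 kT = kT, gamma = gamma, dt = dt),
            class = "toy_system")
}

#' Bonded energy and forces of a toy system
#'
#' Evaluates the harmonic bond and angle terms at the given positions.
#'
#' @param system a [toy_system()].
#' @param positions `N x 3` coordinate matrix (defaults to the system's
#'   atoms).
#' @return List with `U` (potential energy) and `forces` (`N x 3`).
#' @export
bonded_energy_forces <- function(system, positions = NULL) {
  if (!inherits(system, "toy_system")) stop("expected a 'toy_system'")
  if (is.null(positions)) positions <- system$atoms$positions
  n <- nrow(positions)
  F <- matrix(0, n, 3)
  U <- 0
  acc <- function(F, idx, contrib) {
    s <- rowsum(contrib, idx)
    ui <- as.integer(rownames(s))
    F[ui, ] <- F[ui, ] + s
    F
  }
  b <- system$bonds
  if (!is.null(b) && nrow(b) > 0) {
    d <- positions[b$j, , drop = FALSE] - positions[b$i, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dr <- r - b$r0
    U <- U + sum(0.5 * b$k_bond * dr^2)
    # force on i points toward j when the bond is stretched
    fi <- (b$k_bond * dr / pmax(r, 1e-12)) * d
    F <- acc(F, c(b$i, b$j), rbind(fi, -fi))
  }
  a <- system$angles
  if (!is.null(a) && nrow(a) > 0) {
    u <- positions[a$i, , drop = FALSE] - positions[a$j, , drop = FALSE]
    v <- positions[a$k, , drop = FALSE] - positions[a$j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    sth <- sqrt(pmax(1 - cth^2, 1e-12))
    dth <- th - a$theta0
    U <- U + sum(0.5 * a$k_angle * dth^2)
    # dtheta/du, dtheta/dv from differentiating acos(u.v/(|u||v|))
    pref <- -a$k_angle * dth / sth
    gi <- pref * (cth * u / nu^2 - v / (nu * nv))
    gk <- pref * (cth * v / nv^2 - u / (nu * nv))
    F <- acc(F, c(a$i, a$k, a$j), rbind(gi, gk, -gi - gk))
  }
  list(U = U, forces = F)
}

#' One overdamped Brownian step
#'
#' `x <- x + (dt/gamma) F + sqrt(2 kT dt / gamma) xi` with `xi` standard
#' normal per coordinate.  Draws from R's RNG stream, so seeded runs are
#' bit-reproducible.
#'
#' @param system a [toy_system()] (supplies `kT`, `gamma`, `dt`).
#' @param positions `N x 3` coordinate matrix.
#' @param forces `N x 3` total forces; must be finite.
#' @return Updated `N x 3` positions.
#' @export
brownian_step <- function(system, positions, forces) {
  if (any(!is.finite(forces))) {
    stop("non-finite force encountered in Brownian step")
  }
  noise <- if (system$kT > 0) {
    sqrt(2 * system$kT * system$dt / system$gamma) *
      matrix(stats::rnorm(length(positions)), nrow(positions), 3)
  } else 0
  positions + (system$dt / system$gamma) * forces + noise
}

#' Density-guided refinement of a toy system
#'
#' Alternates Brownian steps with density-fitting forces applied every
#' `n_fit` steps (scaled by `n_fit`), updating the adaptive force
#' constant at each fitting application and logging a frame per
#' application.  Terminates early when the maximum per-atom force exceeds
#' the configured threshold (a normal outcome, recorded in the
#' trajectory).
#'
#' @param system a [toy_system()].
#' @param target raw target [density_grid()].
#' @param kind similarity kind or token.
#' @param scaling a [scaling_config()].
#' @param n_steps total number of integration steps.
#' @param seed RNG seed (integer).
#' @param params a [spread_params()]; defaults to
#'   `spread_params(sigma_from_voxel(spacing))` on the target's spacing.
#' @param n_fit fitting-force application period (default 10).
#' @param keep_positions if `TRUE`, keep a copy of the coordinates at
#'   every logged frame.
#' @return An object of class `refinement_trajectory`: a list with `log`
#'   (data frame: frame, time, step, S, ema_S, k, U_ff, U_fit, W,
#'   max_force), `final_positions`, `positions` (optional list),
#'   `termination` (`"completed"` or `"force_limit"`), and `seed`.
#' @export
run_refinement <- function(system, target, kind, scaling, n_steps,
                           seed = 1L, params = NULL, n_fit = 10L,
                           keep_positions = FALSE) {
  if (!inherits(system, "toy_system")) stop("expected a 'toy_system'")
  stopifnot_grid(target)
  kind <- similarity_kind(kind)
  if (!inherits(scaling, "scaling_config")) {
    stop("expected a 'scaling_config'")
  }
  set.seed(as.integer(seed))
  prep <- prepare_target(target, kind)
  if (is.null(params)) {
    params <- spread_params(sigma_from_voxel(mean(target$spacing)))
  }
  ff <- fitting_force_field(kind, prep, params, k = 1, n_fit = n_fit)
  pos <- system$atoms$positions
  atoms <- system$atoms
  state <- scaling_state(scaling$k_init)
  n_fit <- as.integer(n_fit)
  n_frames <- ceiling(n_steps / n_fit)
  log_df <- data.frame(frame = integer(n_frames), time = numeric(n_frames),
                       step = integer(n_frames), S = numeric(n_frames),
                       ema_S = numeric(n_frames), k = numeric(n_frames),
                       U_ff = numeric(n_frames), U_fit = numeric(n_frames),
                       W = numeric(n_frames), max_force = numeric(n_frames))
  pos_list <- if (keep_positions) vector("list", n_frames) else NULL
  frame <- 0L
  S_prev <- NA_real_
  W <- 0
  termination <- "completed"
  f_fit <- matrix(0, nrow(pos), 3)
  for (step in seq_len(n_steps)) {
    atoms$positions <- pos
    bonded <- bonded_energy_forces(system, pos)
    if ((step - 1L) %% n_fit == 0L) {
      ffc <- fitting_forces(ff, atoms)       # unit-k forces and S
      state <- scaling_update(state, ffc$S, scaling)
      f_fit <- apply_multiple_timestep(state$k * ffc$forces, n_fit)
      frame <- frame + 1L
      if (!is.na(S_prev)) W <- W + state$k * (ffc$S - S_prev)
      S_prev <- ffc$S
      max_force <- max(sqrt(rowSums((bonded$forces + f_fit)^2)))
      log_df[frame, ] <- list(frame, step * system$dt, step, ffc$S,
                              state$ema_S, state$k, bonded$U,
                              -state$k * ffc$S, W, max_force)
      if (keep_positions) pos_list[[frame]] <- pos
      if (should_terminate(max_force, scaling)) {
        termination <- "force_limit"
        break
      }
      total <- bonded$forces + f_fit
    } else {
      total <- bonded$forces
    }
    pos <- brownian_step(system, pos, total)
  }
  log_df <- log_df[seq_len(frame), , drop = FALSE]
  if (keep_positions) pos_list <- pos_list[seq_len(frame)]
  structure(list(log = log_df, final_positions = pos,
                 positions = pos_list, termination = termination,
                 seed = as.integer(seed), kind = kind, n_fit = n_fit),
            class = "refinement_trajectory")
}

#' @export
print.refinement_trajectory <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("refinement_trajectory (%s): %d frames, %s\n", x$kind, n,
              x$termination))
  if (n > 0) {
    cat(sprintf("  S: %.5g -> %.5g   k: %.3g -> %.3g   W = %.4g\n",
                x$log$S[1], x$log$S[n], x$log$k[1], x$log$k[n],
                x$log$W[n]))
  }
  invisible(x)
}

#' Effective potential-energy landscape by brute-force scanning
#'
#' Evaluates `U_tot = bond_weight * U_ff + fit_weight * U_fit` (with
#' `U_fit = -S`) for one or two mobile particles over a grid of candidate
#' positions along the x axis, and locates the global minima by
#' exhaustive search.  Used to reproduce the 1D/2D effective-landscape
#' model studies.
#'
#' @param system a [toy_system()] with 1 or 2 atoms (bonds allowed).
#' @param target raw target [density_grid()].
#' @param kind similarity kind or token.
#' @param positions numeric vector of candidate x coordinates; with two
#'   particles the scan covers the full outer grid.
#' @param params a [spread_params()]; for landscape studies choose a
#'   `cutoff_multiple` covering the scan range, since the hard truncation
#'   otherwise imprints itself on the landscape.
#' @param bond_weight weight of the bonded (force-field) energy.
#' @param fit_weight weight of the fitting energy.
#' @return A list with `positions`, `U` (vector or matrix), and `minima`
#'   (matrix of argmin coordinates, one row per global minimum within
#'   `1e-9` of the optimum).
#' @export
landscape_scan <- function(system, target, kind, positions, params,
                           bond_weight = 1, fit_weight = 1) {
  if (!inherits(system, "toy_system")) stop("expected a 'toy_system'")
  n <- n_atoms(system$atoms)
  if (n < 1 || n > 2) {
    stop("landscape scanning supports 1 or 2 particles, got ", n)
  }
  kind <- similarity_kind(kind)
  prep <- prepare_target(target, kind)
  ff <- fitting_force_field(kind, prep, params, k = 1)
  base <- system$atoms$positions
  eval_U <- function(xs) {
    pos <- base
    pos[, 1] <- xs
    atoms <- system$atoms
    atoms$positions <- pos
    geom <- .target_geometry(prep)
    raw <- params; raw$normalize <- FALSE
    model <- spread_density(atoms, geom, raw)
    S <- score(kind, prep, model)$S
    U_ff <- bonded_energy_forces(system, pos)$U
    bond_weight * U_ff + fit_weight * (-S)
  }
  if (n == 1L) {
    U <- vapply(positions, eval_U, numeric(1))
    mins <- which(U <= min(U) + 1e-9)
    minima <- matrix(positions[mins], ncol = 1)
    colnames(minima) <- "x1"
  } else {
    U <- matrix(NA_real_, length(positions), length(positions))
    for (i2 in seq_along(positions)) {
      for (i1 in seq_along(positions)) {
        U[i1, i2] <- eval_U(c(positions[i1], positions[i2]))
      }
    }
    mins <- which(U <= min(U) + 1e-9, arr.ind = TRUE)
    minima <- cbind(x1 = positions[mins[, 1]], x2 = positions[mins[, 2]])
  }
  list(positions = positions, U = U, minima = minima)
}
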