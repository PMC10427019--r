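# Adaptive force-constant scaling and exerted-work accounting.
#
# The force constant is divided by (1 + alpha) when an exponentially
# averaged similarity increases and multiplied by (1 + 2 alpha) when it
# decreases; the asymmetric factors enforce a net increase in similarity
# over time.  The exerted work along a refinement is
# W_fit = integral k dS ~ sum_frames k_frame * dS_frame (only the
# variation of the force constant along the similarity coordinate
# matters).

#' Configuration for adaptive force scaling
#'
#' @param alpha dimensionless scaling increment (>= 0); see
#'   [alpha_from_timescale()] for the time-scale coupling.
#' @param ema_weight weight of the newest score in the exponential moving
#'   average, in (0, 1].  Default 0.1 smooths single-application noise
#'   over roughly ten fitting steps.
#' @param k_init initial force constant (>= 0; 0 gives permanently
#'   unbiased dynamics, useful as a null control).
#' @param f_max termination threshold on the maximum per-atom force
#'   magnitude (> 0): refinement stops once forces are too large to be
#'   compatible with the integration step.
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(alpha, ema_weight = 0.1, k_init = 1,
                           f_max = Inf) {
  if (!is.finite(alpha) || alpha < 0) stop("'alpha' must be >= 0")
  if (!is.finite(ema_weight) || ema_weight <= 0 || ema_weight > 1) {
    stop("'ema_weight' must be in (0, 1]")
  }
  if (!is.numeric(k_init) || is.na(k_init) || k_init < 0) {
    stop("'k_init' must be >= 0")
  }
  if (!is.numeric(f_max) || is.na(f_max) || f_max <= 0) {
    stop("'f_max' must be positive")
  }
  structure(list(alpha = alpha, ema_weight = ema_weight, k_init = k_init,
                 f_max = f_max),
            class = "scaling_config")
}

#' Scaling increment from the simulation time scale
#'
#' `alpha = n_fit * dt / tau`: the increment is set by the interval
#' between fitting-force applications relative to the coupling time scale
#' `tau` that controls how fast the force constant may drift.
#'
#' @param n_fit fitting-force application period (steps, > 0).
#' @param dt smallest integration time step (ps, > 0).
#' @param tau coupling time scale (ps, > 0).
#' @return alpha, dimensionless.
#' @examples
#' alpha_from_timescale(10, 0.002, 4)  # 0.005
#' @export
alpha_from_timescale <- function(n_fit, dt, tau) {
  vals <- c(n_fit, dt, tau)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("'n_fit', 'dt' and 'tau' must all be positive")
  }
  n_fit * dt / tau
}

#' Running state of the adaptive scaling protocol
#'
#' @param k_init initial force constant (>= 0).
#' @param S0 optional similarity of the starting configuration, used to
#'   seed the moving-average baseline.  If omitted, the first update
#'   initializes the baseline without changing `k`.
#' @return An object of class `scaling_state` with elements `k`, `ema_S`,
#'   `prev_ema_S`, `W` and `frame`.
#' @export
scaling_state <- function(k_init, S0 = NULL) {
  if (!is.finite(k_init) || k_init < 0) stop("'k_init' must be >= 0")
  if (!is.null(S0) && !is.finite(S0)) stop("'S0' must be finite")
  structure(list(k = k_init,
                 ema_S = if (is.null(S0)) NA_real_ else S0,
                 prev_ema_S = if (is.null(S0)) NA_real_ else S0,
                 W = 0, frame = 0L),
            class = "scaling_state")
}

#' One adaptive-scaling update
#'
#' Folds the new similarity into the exponential moving average,
#' `ema <- (1 - w) ema + w S_new`, and compares it with the average at the
#' previous fitting step: if the average rose, `k <- k / (1 + alpha)`; if
#' it fell, `k <- k * (1 + 2 alpha)`.  Ties count as an increase (k
#' decreases), biasing the protocol toward gentleness.  Only comparisons
#' of S enter, so the k trajectory is invariant under positive rescaling
#' of the similarity.
#'
#' @param state a [scaling_state()].
#' @param S_new newest similarity score (finite).
#' @param config a [scaling_config()].
#' @return The updated `scaling_state`.
#' @export
scaling_update <- function(state, S_new, config) {
  if (!inherits(state, "scaling_state")) stop("expected 'scaling_state'")
  if (!inherits(config, "scaling_config")) stop("expected 'scaling_config'")
  if (!is.finite(S_new)) {
    stop("non-finite similarity score in adaptive update (state unchanged)")
  }
  w <- config$ema_weight
  if (is.na(state$ema_S)) {
    state$ema_S <- S_new
    state$prev_ema_S <- S_new
    state$frame <- state$frame + 1L
    return(state)
  }
  ema_new <- (1 - w) * state$ema_S + w * S_new
  if (ema_new >= state$prev_ema_S) {
    state$k <- state$k / (1 + config$alpha)
  } else {
    state$k <- state$k * (1 + 2 * config$alpha)
  }
  state$ema_S <- ema_new
  state$prev_ema_S <- ema_new
  state$frame <- state$frame + 1L
  state
}

#' Exerted work from force-constant and similarity traces
#'
#' `W = sum_f k_f * (S_f - S_{f-1})` over logged frames: the discrete
#' form of `integral k dS` along the similarity coordinate.
#'
#' @param k_trace per-frame force constants.
#' @param S_trace per-frame similarity scores (same length, >= 2).
#' @return Total exerted work (energy units of `k`).
#' @export
accumulate_work <- function(k_trace, S_trace) {
  if (length(k_trace) != length(S_trace)) {
    stop("'k_trace' and 'S_trace' must have the same length")
  }
  if (length(S_trace) < 2L) stop("need at least two frames")
  sum(k_trace[-1L] * diff(S_trace))
}

#' Should the refinement terminate on excessive forces?
#'
#' True iff the maximum per-atom force magnitude strictly exceeds the
#' configured threshold `f_max`.
#'
#' @param max_force maximum force magnitude observed (>= 0).
#' @param config a [scaling_config()].
#' @return Logical scalar.
#' @export
should_terminate <- function(max_force, config) {
  if (!inherits(config, "scaling_config")) stop("expected 'scaling_config'")
  if (!is.numeric(max_force) || is.na(max_force) || max_force < 0) {
    stop("'max_force' must be a nonnegative number")
  }
  isTRUE(max_force > config$f_max)
}
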