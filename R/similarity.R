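# Similarity scores between a target density and a model density, and
# their per-voxel derivatives.
#
# All scores are larger-is-better and the fitting potential is
# U_fit = -k * S, so fitting forces follow +k * grad S.  The two
# relative-entropy kinds compare probability densities: the target is
# preprocessed (negatives clipped, normalized to unit sum) and the model
# is the unit-sum spread density.  Scale parameters of the underlying
# noise models (Dirichlet/Poisson) are not estimated; they are absorbed
# into the force constant k.

.sim_kinds <- c("inner-product", "cross-correlation",
                "relative-entropy", "relative-entropy-swapped")
.sim_tokens <- c(ip = "inner-product", cc = "cross-correlation",
                 re = "relative-entropy", res = "relative-entropy-swapped")

# Positivity floor for log arguments, relative to a unit-sum density.
# Truncated spreading produces exact zeros; without the floor any
# non-overlapping voxel sends a relative-entropy score to -Inf.
.sim_eps <- 1e-12

#' Resolve a similarity-kind name or short token
#'
#' Accepts the full kind names (`"inner-product"`, `"cross-correlation"`,
#' `"relative-entropy"`, `"relative-entropy-swapped"`) or the short CLI
#' tokens (`"ip"`, `"cc"`, `"re"`, `"res"`).
#'
#' @param kind character scalar.
#' @return The canonical kind name.
#' @export
similarity_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L) {
    stop("'kind' must be a single string")
  }
  if (kind %in% names(.sim_tokens)) return(unname(.sim_tokens[kind]))
  match.arg(kind, .sim_kinds)
}

.is_probability_kind <- function(kind) {
  kind %in% c("relative-entropy", "relative-entropy-swapped")
}

#' Preprocess a target density for a similarity kind
#'
#' For the relative-entropy kinds the target is treated as a probability
#' density: negative voxel values are clipped to zero and the map is
#' normalized to unit sum; the support mask marks strictly positive
#' voxels.  For inner-product and cross-correlation the raw map is passed
#' through unchanged and every voxel participates.
#'
#' @param grid a [density_grid()] with the raw target map.
#' @param kind similarity kind (see [similarity_kind()]).
#' @return An object of class `prepared_target` with elements `values`,
#'   `kind`, `support` and the grid geometry.
#' @export
prepare_target <- function(grid, kind) {
  stopifnot_grid(grid)
  kind <- similarity_kind(kind)
  v <- grid$values
  if (.is_probability_kind(kind)) {
    v[v < 0] <- 0
    tot <- sum(v)
    if (tot <= 0) {
      stop("no positive density: cannot prepare an all-nonpositive map ",
           "for a probability-based similarity kind")
    }
    v <- v / tot
    support <- v > 0
  } else {
    support <- array(TRUE, dim(v))
  }
  structure(list(values = v, kind = kind, support = support,
                 origin = grid$origin, spacing = grid$spacing),
            class = "prepared_target")
}

#' @export
print.prepared_target <- function(x, ...) {
  cat(sprintf("prepared_target (%s): %s voxels, %d in support\n", x$kind,
              paste(dim(x$values), collapse = " x "), sum(x$support)))
  invisible(x)
}

.check_score_args <- function(kind, target, model) {
  if (!inherits(target, "prepared_target")) {
    stop("'target' must come from prepare_target()")
  }
  kind <- similarity_kind(kind)
  if (!identical(kind, target$kind)) {
    stop("target was prepared for kind '", target$kind,
         "', not '", kind, "'")
  }
  m <- if (is_density_grid(model)) model$values else model
  if (is.null(dim(m))) m <- array(m, c(length(m), 1L, 1L))
  if (!identical(dim(m), dim(target$values))) {
    stop("model grid shape ", paste(dim(m), collapse = "x"),
         " does not match target ",
         paste(dim(target$values), collapse = "x"))
  }
  list(kind = kind, m = m)
}

# The relative-entropy kinds compare the *normalized* model density.  The
# normalization to unit sum is applied here (idempotent for an already
# unit-sum spread), and its Jacobian is propagated by score_derivative so
# that forces are exact gradients of the score.
.normalize_model <- function(m) {
  tot <- sum(m)
  if (tot > 0) list(m = m / tot, tot = tot) else list(m = m, tot = 0)
}

#' Similarity score between a prepared target and a model density
#'
#' With `rho` the prepared target and `rho_s` the model:
#' * inner-product: `S = sum(rho * rho_s)`;
#' * cross-correlation: cosine similarity
#'   `S = sum(rho * rho_s) / sqrt(sum(rho^2) * sum(rho_s^2))` (no mean
#'   subtraction), in `[-1, 1]`;
#' * relative-entropy: `S = sum_{rho>0} rho * log(max(rho_s, eps)/rho)`,
#'   the negative Kullback-Leibler divergence `-KL(rho || rho_s)`, with
#'   domain `[-Inf, 0]` and perfect agreement at 0;
#' * relative-entropy-swapped:
#'   `S = sum_{rho_s>0} rho_s * log(max(rho, eps))`, the Dirichlet-model
#'   score (an inner product against the log target).
#'
#' For the relative-entropy kinds the model is normalized to unit sum
#' internally, and `eps = 1e-12` floors log arguments where the truncated
#' spread is exactly zero.
#'
#' @param kind similarity kind or short token.
#' @param target a `prepared_target` from [prepare_target()].
#' @param model a [density_grid()] (or array) on the same grid, normally
#'   the output of [spread_density()].
#' @return A list of class `score_value` with elements `S` and `kind`.
#' @export
score <- function(kind, target, model) {
  ck <- .check_score_args(kind, target, model)
  kind <- ck$kind; m <- ck$m; rho <- target$values
  S <- switch(kind,
    "inner-product" = sum(rho * m),
    "cross-correlation" = {
      den <- sqrt(sum(rho^2) * sum(m^2))
      if (den == 0) stop("cross-correlation undefined for an all-zero map")
      sum(rho * m) / den
    },
    "relative-entropy" = {
      mm <- .normalize_model(m)$m
      sup <- target$support
      sum(rho[sup] * log(pmax(mm[sup], .sim_eps) / rho[sup]))
    },
    "relative-entropy-swapped" = {
      mm <- .normalize_model(m)$m
      pos <- mm > 0
      sum(mm[pos] * log(pmax(rho[pos], .sim_eps)))
    })
  structure(list(S = S, kind = kind), class = "score_value")
}

#' @export
print.score_value <- function(x, ...) {
  cat(sprintf("S (%s) = %.6g\n", x$kind, x$S))
  invisible(x)
}

#' Per-voxel derivative of a similarity score
#'
#' Returns `dS/d rho_s_v` for every voxel, as an array on the model grid.
#' For the relative-entropy kinds the derivative is taken with respect to
#' the *raw* model values, i.e. the Jacobian of the internal unit-sum
#' normalization is included (without it forces would acquire a spurious
#' uniform component).  Where the positivity floor binds, the local
#' derivative is zero.
#'
#' @inheritParams score
#' @return Numeric array of per-voxel derivatives.
#' @export
score_derivative <- function(kind, target, model) {
  ck <- .check_score_args(kind, target, model)
  kind <- ck$kind; m <- ck$m; rho <- target$values
  switch(kind,
    "inner-product" = rho,
    "cross-correlation" = {
      a <- sum(rho * m)
      nr2 <- sum(rho^2); nm2 <- sum(m^2)
      den <- sqrt(nr2 * nm2)
      if (den == 0) stop("cross-correlation undefined for an all-zero map")
      rho / den - (a / (den * nm2)) * m
    },
    "relative-entropy" = {
      nm <- .normalize_model(m)
      if (nm$tot == 0) return(array(0, dim(m)))
      mm <- nm$m
      g <- array(0, dim(m))
      idx <- target$support & (mm > .sim_eps)
      g[idx] <- rho[idx] / mm[idx]
      (g - sum(g * mm)) / nm$tot
    },
    "relative-entropy-swapped" = {
      nm <- .normalize_model(m)
      if (nm$tot == 0) return(array(0, dim(m)))
      mm <- nm$m
      g <- log(pmax(rho, .sim_eps))
      (g - sum(g * mm)) / nm$tot
    })
}
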