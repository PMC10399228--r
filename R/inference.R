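#' Scaled biological noise covariance
#'
#' Build the 3x3 covariance matrix `S` used to normalize the reduced
#' sensory-conflict vector `(||e_a||, ||e_f||, ||e_omega||)` into the NIS
#' statistic. The three standard deviations are in the units of the
#' corresponding conflict component: g units for the acceleration conflict,
#' dimensionless (radian-scaled axis) for the GIF-direction conflict, and
#' rad/s for the angular-velocity conflict.
#'
#' The defaults control how sharply gravity-magnitude hypotheses are
#' discriminated (and therefore how fast adaptation proceeds): with the
#' default observer gains a steady magnitude mismatch `dg` leaves an
#' acceleration conflict of about `0.2 * dg`, so `sigma = 0.03` g makes
#' adjacent 0.01 g grid hypotheses statistically indistinguishable while
#' mismatches of a few hundredths of a g are still selected against.
#'
#' @param sigma Length-3 vector of conflict standard deviations
#'   (acceleration, GIF direction, angular velocity).
#' @param S Optionally, a full 3x3 symmetric positive-definite matrix;
#'   overrides `sigma`.
#' @return A 3x3 positive-definite matrix of class `grav_noise_cov`.
#' @export
#' @examples
#' S <- noise_covariance()
#' nis(c(0, 0, 0), S)
noise_covariance <- function(sigma = c(0.03, 0.05, 0.02), S = NULL) {
  if (is.null(S)) {
    stopifnot(is.numeric(sigma), length(sigma) == 3, all(sigma > 0))
    S <- diag(sigma^2, nrow = 3)
  }
  validate_noise_cov(S)
  structure(S, class = c("grav_noise_cov", "matrix", "array"))
}

validate_noise_cov <- function(S) {
  if (!is.matrix(S) || !identical(dim(S), c(3L, 3L)) || !is.numeric(S)) {
    abort("`S` must be a numeric 3x3 matrix.")
  }
  if (max(abs(S - t(S))) > 1e-12) {
    abort("`S` must be symmetric (within 1e-12).")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    abort("`S` must be positive definite; got a non-positive eigenvalue.")
  }
  invisible(S)
}

#' Normalized innovation squared (NIS)
#'
#' Collapse a reduced conflict vector `e` into the scalar quadratic form
#' `t(e) %*% solve(S) %*% e`. Zero if and only if the conflict is zero.
#'
#' @param e Length-3 reduced conflict vector, or a 3-row matrix of conflict
#'   vectors (one column per observer).
#' @param S Noise covariance from [noise_covariance()].
#' @return Non-negative scalar (or vector, one value per column of `e`).
#' @export
nis <- function(e, S) {
  validate_noise_cov(S)
  e <- as.matrix(e)
  if (nrow(e) != 3) abort("`e` must have 3 rows (or be a length-3 vector).")
  if (any(!is.finite(e))) abort("`e` must be finite.")
  R <- chol(S)
  z <- backsolve(R, e, transpose = TRUE)
  out <- colSums(z^2)
  if (ncol(e) == 1) out <- out[[1]]
  out
}

#' Measurement likelihood of a sensory conflict
#'
#' Gaussian density of the reduced conflict vector under zero mean and
#' covariance `S`: `(2*pi)^(-3/2) * det(S)^(-1/2) * exp(-nis/2)`. This is
#' the per-hypothesis measurement likelihood `p(y | x)` that drives the
#' particle weights; it is maximal at zero conflict and strictly decreasing
#' in the NIS.
#'
#' @inheritParams nis
#' @param log If `TRUE`, return the log density (the engine works in log
#'   space because the density underflows at large NIS).
#' @return Density value(s), or log density if `log = TRUE`.
#' @export
conflict_likelihood <- function(e, S, log = FALSE) {
  eps <- nis(e, S)
  ll <- log_likelihood_const(S) - eps / 2
  if (log) ll else exp(ll)
}

# log[(2*pi)^(-3/2) det(S)^(-1/2)]: the log density at zero conflict.
log_likelihood_const <- function(S) {
  R <- chol(S)
  -1.5 * log(2 * pi) - sum(log(diag(R)))
}

#' Gravity-hypothesis grid
#'
#' The discrete support for gravity-magnitude hypotheses. The default grid
#' spans 0.05 to 5 g at a coarseness of 1/100 g, covering all simulated
#' levels (0.5 to 4 g) while excluding 0 g (microgravity transitions involve
#' additional reinterpretation mechanisms outside this model's scope).
#'
#' @param g_min,g_max Grid bounds in g units (`g_min >= 0`).
#' @param step Grid spacing in g units.
#' @return An object of class `gravity_grid` with elements `g_min`, `g_max`,
#'   `step`, `values` (all bin centres) and `n`.
#' @export
gravity_grid <- function(g_min = 0.05, g_max = 5, step = 0.01) {
  stopifnot(g_min >= 0, step > 0, g_max > g_min)
  k <- (g_max - g_min) / step
  if (abs(k - round(k)) > 1e-9) {
    abort("(g_max - g_min) must be an integer multiple of `step`.")
  }
  n <- as.integer(round(k)) + 1L
  structure(
    list(
      g_min = g_min, g_max = g_max, step = step,
      values = g_min + step * (seq_len(n) - 1L), n = n
    ),
    class = "gravity_grid"
  )
}

#' @export
print.gravity_grid <- function(x, ...) {
  cat(sprintf(
    "<gravity_grid> [%g, %g] g, step %g g (%d bins)\n",
    x$g_min, x$g_max, x$step, x$n
  ))
  invisible(x)
}

# Bin index of gravity value(s) on the grid; error if off-grid (beyond
# tol), used to enforce that particles stay grid-aligned.
grid_bin <- function(grid, x, tol = 1e-9) {
  idx <- (x - grid$g_min) / grid$step
  r <- round(idx)
  if (any(abs(idx - r) > tol / grid$step) ||
      any(r < 0) || any(r > grid$n - 1L)) {
    abort("gravity value off-grid.")
  }
  as.integer(r) + 1L
}

# Nearest grid value (used to snap an initial gravity level onto the grid).
grid_snap <- function(grid, x) {
  v <- grid$g_min + grid$step * round((x - grid$g_min) / grid$step)
  pmin(pmax(v, grid$g_min), grid$g_max)
}

#' Construct a particle set
#'
#' A particle set is a tibble with one row per gravity-magnitude hypothesis:
#' `x` (hypothesis, g units), `w` (posterior weight) and `lik` (last
#' measurement likelihood). Weights are normalized to sum to one.
#'
#' @param x Numeric vector of hypotheses.
#' @param w Weights (default uniform); normalized internally.
#' @param lik Last likelihoods (default `NA`).
#' @return A tibble of class `grav_particles`.
#' @export
particle_set <- function(x, w = NULL, lik = NA_real_) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  if (is.null(w)) w <- rep(1 / length(x), length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  out <- tibble::tibble(x = x, w = w / sum(w), lik = lik)
  class(out) <- c("grav_particles", class(out))
  out
}

#' Reweight particles by measurement likelihoods
#'
#' With bootstrap resampling at every iteration the recursive weight update
#' reduces to weights proportional to the current likelihoods, normalized to
#' unit total mass.
#'
#' @param particles A [particle_set()].
#' @param liks Non-negative likelihoods, one per particle.
#' @return The particle set with `w` and `lik` replaced.
#' @export
reweight <- function(particles, liks) {
  stopifnot(is.numeric(liks), length(liks) == nrow(particles))
  if (any(liks < 0) || any(!is.finite(liks))) {
    abort("`liks` must be finite and non-negative.")
  }
  total <- sum(liks)
  if (total == 0) {
    abort(
      "degenerate likelihoods: all particle likelihoods are zero (the engine handles this in log space)."
    )
  }
  particles$w <- liks / total
  particles$lik <- liks
  particles
}

#' Posterior mass over the gravity grid
#'
#' Aggregate particle weights into per-bin posterior mass. Every particle
#' must sit exactly on a grid value.
#'
#' @param particles A [particle_set()].
#' @param grid A [gravity_grid()].
#' @return A tibble with columns `x` (bin value) and `mass`, one row per
#'   grid bin; total mass is 1 (up to the particle-weight normalization).
#' @export
posterior_on_grid <- function(particles, grid) {
  if (nrow(particles) == 0) abort("empty particle set.")
  bins <- grid_bin(grid, particles$x)
  mass <- numeric(grid$n)
  agg <- rowsum(particles$w, bins)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  tibble::tibble(x = grid$values, mass = mass)
}

#' MAP gravity estimate
#'
#' The grid value with maximal posterior mass; ties are broken toward the
#' lowest gravity value so the estimator is deterministic.
#'
#' @param posterior A tibble with columns `x` and `mass`, as returned by
#'   [posterior_on_grid()].
#' @return A single gravity magnitude (g units).
#' @export
map_estimate <- function(posterior) {
  stopifnot(all(c("x", "mass") %in% names(posterior)))
  m <- posterior$mass
  if (!any(m > 0)) abort("all-zero posterior.")
  posterior$x[which.max(m)]
}
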