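#' Short-term memory (jitter search) state
#'
#' Tracks the exponentially weighted history of maximum likelihood (HML)
#' and the derived jitter standard deviation used by the short-term-memory
#' Gaussian search. High recent likelihoods shrink the jitter (exploitation:
#' new hypotheses stay near current ones); a collapse of likelihoods lets
#' HML decay and the jitter widen (exploration).
#'
#' @param hml Initial history of maximum likelihood (density units). The
#'   engine initializes it at the likelihood of a zero-conflict measurement
#'   (its maximum possible value) so simulations start fully adapted.
#' @param f Forgetting factor in `[0, 1]`; values near 1 weigh past maxima
#'   more heavily, so a sustained build-up of conflict (not a single noisy
#'   measurement) is needed to trigger exploration.
#' @param chi1 Sensitivity exponent of the inverse-power law
#'   `sigma = c_jitter / hml^chi1`.
#' @param c_jitter Proportionality constant of that law (the paper-level
#'   theory states only the proportionality; the constant is a model
#'   parameter here).
#' @param sigma_min,sigma_max Clip bounds on the jitter width (g units),
#'   preventing degenerate zero-width or grid-spanning searches.
#' @return A list of class `grav_stm` with the parameters plus the current
#'   `sigma`.
#' @export
stm_state <- function(hml = 0, f = 0.8, chi1 = 1, c_jitter = 10,
                      sigma_min = 0.005, sigma_max = 1) {
  stopifnot(
    hml >= 0, f >= 0, f <= 1, chi1 > 0, c_jitter > 0,
    sigma_min > 0, sigma_max >= sigma_min
  )
  stm <- structure(
    list(
      hml = hml, f = f, chi1 = chi1, c_jitter = c_jitter,
      sigma_min = sigma_min, sigma_max = sigma_max, sigma = NA_real_
    ),
    class = "grav_stm"
  )
  jitter_sigma(stm)
}

#' Update the history of maximum likelihood
#'
#' Exponentially weighted average of the per-step maximum particle
#' likelihood: `HML_k = (1 - 1/(1+f)) * HML_{k-1} + (1/(1+f)) * max(liks)`.
#'
#' @param stm A [stm_state()].
#' @param liks Non-empty vector of per-particle likelihood densities.
#' @return The updated `grav_stm` (with `sigma` refreshed).
#' @export
update_hml <- function(stm, liks) {
  if (length(liks) == 0) abort("`liks` must be non-empty.")
  if (any(liks < 0)) abort("`liks` must be non-negative.")
  a <- 1 / (1 + stm$f)
  stm$hml <- (1 - a) * stm$hml + a * max(liks)
  jitter_sigma(stm)
}

#' Jitter width from the likelihood history
#'
#' `sigma = clip(c_jitter / hml^chi1, sigma_min, sigma_max)`; a vanished
#' likelihood history maps to the maximal (fully exploratory) width.
#'
#' @param stm A [stm_state()].
#' @return The `grav_stm` with `sigma` recomputed.
#' @export
jitter_sigma <- function(stm) {
  sigma <- if (stm$hml <= 0) {
    stm$sigma_max
  } else {
    stm$c_jitter / stm$hml^stm$chi1
  }
  stm$sigma <- min(max(sigma, stm$sigma_min), stm$sigma_max)
  stm
}

#' Short-term-memory transition density
#'
#' Gaussian density centred on the parent hypothesis, evaluated on the
#' gravity grid and renormalized to unit mass over the grid.
#'
#' @param parent_x Parent hypothesis (g units).
#' @param sigma Jitter standard deviation (g units, `> 0`).
#' @param grid A [gravity_grid()].
#' @return Numeric vector of bin masses summing to 1.
#' @export
stm_density <- function(parent_x, sigma, grid) {
  stopifnot(sigma > 0, is.finite(parent_x))
  d <- dnorm(grid$values, mean = parent_x, sd = sigma)
  s <- sum(d)
  if (s == 0) {
    # parent far outside the grid relative to sigma: fall back to the
    # nearest bin so the density remains proper.
    d[which.min(abs(grid$values - parent_x))] <- 1
    s <- 1
  }
  d / s
}

#' Long-term memory state
#'
#' Time-stamped buffer of harmonious central estimates: gravity levels whose
#' central NIS fell below the harmony threshold `nu`. Entries older than the
#' retention window `t_wind` are pruned, so learned states age out (and are
#' eventually unlearned) when the model stops visiting them.
#'
#' @param nu NIS harmony threshold. The default `2*log(2)` is the NIS at
#'   which the measurement likelihood falls to half its zero-conflict
#'   maximum.
#' @param t_wind Retention window (model seconds).
#' @param dk Filter step (model seconds); `t_wind / dk` must be integral and
#'   defines `n_wind`, the window length in filter steps.
#' @return A list of class `grav_ltm` with `times`, `values`, `nu`,
#'   `t_wind`, `dk`, `n_wind`.
#' @export
ltm_state <- function(nu = 2 * log(2), t_wind = 300, dk = 0.5) {
  stopifnot(nu > 0, t_wind > 0, dk > 0)
  n_wind <- t_wind / dk
  if (abs(n_wind - round(n_wind)) > 1e-9) {
    abort("`t_wind` must be an integer multiple of `dk`.")
  }
  structure(
    list(
      times = numeric(0), values = numeric(0),
      nu = nu, t_wind = t_wind, dk = dk, n_wind = as.integer(round(n_wind))
    ),
    class = "grav_ltm"
  )
}

#' Record a harmonious state and prune the window
#'
#' If the central NIS is below the harmony threshold, append the central
#' estimate with the current timestamp; then drop every entry older than
#' `t_now - t_wind`.
#'
#' @param ltm A [ltm_state()].
#' @param estimate Central (MAP) gravity estimate (g units).
#' @param central_nis Central observer's NIS at this step.
#' @param t_now Current model time (non-decreasing across calls).
#' @return The updated `grav_ltm`.
#' @export
update_harmonious <- function(ltm, estimate, central_nis, t_now) {
  if (length(ltm$times) && t_now < ltm$times[length(ltm$times)]) {
    abort("`t_now` must be non-decreasing across calls.")
  }
  if (is.finite(central_nis) && central_nis < ltm$nu) {
    ltm$times <- c(ltm$times, t_now)
    ltm$values <- c(ltm$values, estimate)
  }
  keep <- ltm$times >= t_now - ltm$t_wind
  ltm$times <- ltm$times[keep]
  ltm$values <- ltm$values[keep]
  ltm
}

#' Long-term-memory density over the grid
#'
#' Each harmonious entry contributes a single-grid-bin point mass of
#' `1/n_wind`; the total mass equals the fraction of the retention window
#' spent in harmonious states (so it is at most 1, and 0 when nothing is
#' remembered).
#'
#' @param ltm A [ltm_state()] (already pruned by [update_harmonious()]).
#' @param grid A [gravity_grid()].
#' @return Numeric vector of bin masses with total in `[0, 1]`.
#' @export
ltm_density <- function(ltm, grid) {
  d <- numeric(grid$n)
  if (length(ltm$values)) {
    bins <- grid_bin(grid, grid_snap(grid, ltm$values))
    tab <- tabulate(bins, nbins = grid$n)
    d <- tab / ltm$n_wind
  }
  d
}

#' Long-term-memory priority weight
#'
#' Sigmoid map from the jitter width to the LTM mixture weight:
#' `W = 1/(1 + exp(-sigma * chi2)) - 1/2`, so `W` runs from 0 (pure
#' exploitation: short-term search only) toward 1/2 (exploration: long-term
#' memory weighted almost equally) and never reaches 1/2.
#'
#' @param sigma Jitter standard deviation (g units, `>= 0`).
#' @param chi2 Sigmoid slope (1 / g units).
#' @return `W` in `[0, 0.5)`.
#' @export
mixture_weight <- function(sigma, chi2) {
  stopifnot(all(sigma >= 0), chi2 > 0)
  1 / (1 + exp(-sigma * chi2)) - 0.5
}

#' Transition-kernel parameters
#'
#' Holds the sigmoid slope `chi2` and the shared gravity grid used by the
#' mixture state-transition density. One `W` is computed per filter step
#' from the shared jitter width (HML is defined over all particles'
#' likelihoods), not per particle.
#'
#' @param chi2 Sigmoid slope of [mixture_weight()].
#' @param grid A [gravity_grid()].
#' @return A list of class `grav_transition`.
#' @export
transition_model <- function(chi2 = 4, grid = gravity_grid()) {
  stopifnot(chi2 > 0, inherits(grid, "gravity_grid"))
  structure(list(chi2 = chi2, grid = grid), class = "grav_transition")
}

#' Mixture state-transition density
#'
#' Pointwise mixture `(1 - W) * p_STM + W * p_LTM`, renormalized to unit
#' mass over the grid. With an empty long-term memory the result equals the
#' short-term density exactly (same code path, bitwise), so disabling LTM
#' cannot perturb a run in which nothing has been learned.
#'
#' @param parent_x Parent hypothesis (g units).
#' @param stm A [stm_state()] (supplies `sigma`).
#' @param ltm A [ltm_state()].
#' @param tm A [transition_model()].
#' @return Numeric vector of bin masses summing to 1.
#' @export
transition_density <- function(parent_x, stm, ltm, tm) {
  p_stm <- stm_density(parent_x, stm$sigma, tm$grid)
  if (!length(ltm$values)) {
    return(p_stm)
  }
  W <- mixture_weight(stm$sigma, tm$chi2)
  d <- (1 - W) * p_stm + W * ltm_density(ltm, tm$grid)
  s <- sum(d)
  if (s <= 0) abort("zero total transition mass.")
  d / s
}

#' Sample new hypotheses from the transition kernel
#'
#' Draw one grid-aligned child hypothesis per (post-resampling) parent from
#' its conditional transition density. Parents sharing a value share a
#' density evaluation, so sampling cost scales with the number of distinct
#' parent values, not the particle count.
#'
#' @param parents Numeric vector of parent hypotheses, or a
#'   [particle_set()] (its `x` column is used).
#' @param stm,ltm,tm Memory states and kernel parameters as in
#'   [transition_density()].
#' @return Numeric vector of child hypotheses, on-grid, one per parent.
#' @export
sample_transitions <- function(parents, stm, ltm, tm) {
  if (is.data.frame(parents)) parents <- parents$x
  stopifnot(is.numeric(parents), length(parents) >= 1)
  out <- numeric(length(parents))
  for (px in unique(parents)) {
    sel <- which(parents == px)
    dens <- transition_density(px, stm, ltm, tm)
    draws <- sample.int(tm$grid$n, length(sel), replace = TRUE, prob = dens)
    out[sel] <- tm$grid$values[draws]
  }
  out
}
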