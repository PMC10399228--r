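#' Engine configuration
#'
#' All constants of the particle-filter engine in one validated object.
#' Defaults reproduce the canonical simulation conditions: 100 particles on
#' a 1/100 g grid, sensory noise power `1e-8`, sinusoidal roll-tilt
#' stimulus, observer with differential otolith weighting on the interaural
#' axis, and the short/long-term memory constants documented in the methods
#' vignette.
#'
#' @param n_particles Particle count `N_s` (`>= 1`).
#' @param grid A [gravity_grid()].
#' @param observer A [observer_params()]. The engine default down-weights
#'   the interaural otolith conflict component (`oto_weights = c(1, 0.4,
#'   1)`) so the central observer reproduces hyper-gravity tilt
#'   overestimation.
#' @param S A [noise_covariance()].
#' @param noise_power Sensory noise power; see [add_sensory_noise()].
#' @param f,chi1,c_jitter,sigma_min,sigma_max Short-term-memory constants;
#'   see [stm_state()].
#' @param chi2 Sigmoid slope of the LTM priority weight; see
#'   [mixture_weight()].
#' @param nu,t_wind Long-term-memory constants; see [ltm_state()].
#' @param dt Observer integration step (model seconds).
#' @param dk Filter step (model seconds); must be an integer multiple of
#'   `dt`.
#' @param ltm_enabled Logical; disable to run the short-term-memory-only
#'   model.
#' @param resample `"multinomial"` (bootstrap) or `"systematic"`.
#' @return A list of class `grav_config`.
#' @export
engine_config <- function(n_particles = 100,
                          grid = gravity_grid(),
                          observer = observer_params(oto_weights = c(1, 0.4, 1)),
                          S = noise_covariance(),
                          noise_power = 1e-8,
                          f = 0.8, chi1 = 1, c_jitter = 10,
                          sigma_min = 0.005, sigma_max = 1,
                          chi2 = 4,
                          nu = 2 * log(2), t_wind = 300,
                          dt = 0.05, dk = 0.5,
                          ltm_enabled = TRUE,
                          resample = c("multinomial", "systematic")) {
  resample <- match.arg(resample)
  stopifnot(
    n_particles >= 1, inherits(grid, "gravity_grid"),
    inherits(observer, "grav_observer_params"),
    noise_power >= 0, dt > 0, dk >= dt
  )
  m <- dk / dt
  if (abs(m - round(m)) > 1e-9) {
    abort("`dk` must be an integer multiple of `dt`.")
  }
  validate_noise_cov(S)
  observer$dt <- dt
  structure(
    list(
      n_particles = as.integer(n_particles), grid = grid,
      observer = observer, S = S, noise_power = noise_power,
      f = f, chi1 = chi1, c_jitter = c_jitter,
      sigma_min = sigma_min, sigma_max = sigma_max, chi2 = chi2,
      nu = nu, t_wind = t_wind, dt = dt, dk = dk,
      substeps = as.integer(round(m)),
      ltm_enabled = isTRUE(ltm_enabled), resample = resample
    ),
    class = "grav_config"
  )
}

# Shared preparation: truth kinematics, clean afference, noise injection.
prepare_afference <- function(motion, config, noise_seed) {
  if (abs(attr(motion, "dt") - config$dt) > 1e-12) {
    abort("motion `dt` must equal the engine `dt`.")
  }
  kin <- head_kinematics(motion)
  aff <- vestibular_afference(kin, config$observer)
  aff <- add_sensory_noise(aff, config$noise_power, seed = noise_seed)
  list(
    kin = kin,
    canal = rbind(aff$canal_x, aff$canal_y, aff$canal_z),
    oto = rbind(aff$oto_x, aff$oto_y, aff$oto_z)
  )
}

resample_indices <- function(w, n, scheme) {
  if (scheme == "multinomial") {
    sample.int(length(w), n, replace = TRUE, prob = w)
  } else {
    u <- (runif(1) + seq_len(n) - 1) / n
    findInterval(u, cumsum(w) / sum(w)) + 1L
  }
}

#' Simulate gravity adaptation with the memory-augmented particle filter
#'
#' Runs the full loop over a motion profile: the observer bank (one
#' magnitude-constrained observer per grid value) is advanced on the shared
#' noisy afference; each particle reads the conflict of its grid observer;
#' likelihoods (computed in log space), weights, the posterior over the
#' grid and its MAP are formed; the central observer is the bank observer
#' at the MAP value and supplies the central NIS and tilt perception; the
#' likelihood history, jitter width and LTM priority weight are updated;
#' harmonious central estimates are stored in long-term memory; and new
#' hypotheses are drawn from the mixture transition kernel after bootstrap
#' resampling.
#'
#' Three named RNG streams (noise, resampling, transition) are derived from
#' `seed`, so runs are bit-reproducible and toggling `ltm_enabled` leaves
#' the sensor-noise realization unchanged (paired comparisons).
#'
#' @param motion A `grav_motion` tibble (see [roll_tilt_motion()],
#'   [set_gravity_schedule()]).
#' @param config A [engine_config()].
#' @param seed Master seed (integer).
#' @param keep_particles Keep per-step particle positions and weights
#'   (matrices `N_s` x steps) in the result.
#' @param keep_posterior Keep the per-step posterior over the full grid
#'   (matrix bins x steps); needed for comparisons against
#'   [grid_bayes_reference()].
#' @return An object of class `grav_sim`: list with `steps` (per-filter-step
#'   tibble), optional `particles`/`weights`/`posterior` matrices,
#'   `ltm_final`, `config`, `seed`, `schedule`.
#' @export
#' @examples
#' m <- roll_tilt_motion(duration = 30) |>
#'   set_gravity_schedule(data.frame(start = c(0, 15), level = c(1, 4)))
#' sim <- simulate_adaptation(m, engine_config(), seed = 1)
#' tail(tidy(sim)$map_estimate)
simulate_adaptation <- function(motion, config = engine_config(), seed = 1,
                                keep_particles = TRUE,
                                keep_posterior = FALSE) {
  stopifnot(inherits(config, "grav_config"))
  seeds <- derive_stream_seeds(seed)
  prep <- prepare_afference(motion, config, seeds[["noise"]])
  grid <- config$grid
  m <- config$substeps
  n_steps <- (nrow(motion) - 1L) %/% m
  if (n_steps < 1) abort("motion shorter than one filter step.")

  # initial conditions: everything starts adapted to the initial level
  g0 <- motion$g_true[1]
  x0 <- grid_snap(grid, g0)
  if (abs(x0 - g0) > 1e-9) {
    warn(sprintf("initial gravity %.4f g is off-grid; snapped to %.2f g.", g0, x0))
  }
  u0 <- c(prep$kin$ux[1], prep$kin$uy[1], prep$kin$uz[1])
  bank <- new_observer_bank(grid$values, config$observer, u0)
  x <- rep(x0, config$n_particles)

  logc <- log_likelihood_const(config$S)
  hml0 <- exp(logc) # zero-conflict likelihood: start in exploitation
  stm <- stm_state(
    hml = hml0, f = config$f, chi1 = config$chi1,
    c_jitter = config$c_jitter,
    sigma_min = config$sigma_min, sigma_max = config$sigma_max
  )
  ltm <- ltm_state(nu = config$nu, t_wind = config$t_wind, dk = config$dk)
  tm <- transition_model(chi2 = config$chi2, grid = grid)
  rs_stream <- new_rng_stream(seeds[["resample"]])
  tr_stream <- new_rng_stream(seeds[["transition"]])

  Sinv_chol <- chol(config$S)
  schedule <- attr(motion, "schedule")
  levels <- if (is.null(schedule)) unique(motion$g_true) else unique(schedule$level)

  rec <- list(
    t = numeric(n_steps), map = numeric(n_steps),
    max_lik = numeric(n_steps), hml = numeric(n_steps),
    sigma = numeric(n_steps), W = numeric(n_steps),
    central_nis = numeric(n_steps), roll_true = numeric(n_steps),
    roll_perceived = numeric(n_steps), g_true = numeric(n_steps),
    ltm_mass = numeric(n_steps), ess = numeric(n_steps)
  )
  ltm_level_mass <- matrix(
    0, n_steps, length(levels),
    dimnames = list(NULL, paste0("ltm_mass_", levels))
  )
  P <- if (keep_particles) matrix(NA_real_, config$n_particles, n_steps)
  Wt <- if (keep_particles) matrix(NA_real_, config$n_particles, n_steps)
  Post <- if (keep_posterior) matrix(NA_real_, grid$n, n_steps)

  for (k in seq_len(n_steps)) {
    idx <- ((k - 1L) * m + 2L):(k * m + 1L)
    bank <- bank_advance(bank, prep$canal[, idx, drop = FALSE],
      prep$oto[, idx, drop = FALSE],
      dt = config$dt
    )
    red <- bank$conflict$reduced
    z <- backsolve(Sinv_chol, red, transpose = TRUE)
    eps_bins <- colSums(z^2)
    loglik_bins <- logc - eps_bins / 2
    lik_bins <- exp(loglik_bins)

    pbin <- grid_bin(grid, x)
    ll <- loglik_bins[pbin]
    wraw <- exp(ll - max(ll))
    if (!all(is.finite(wraw)) || sum(wraw) == 0) {
      abort("degenerate particle likelihoods (non-finite NIS).")
    }
    w <- wraw / sum(wraw)

    mass <- numeric(grid$n)
    agg <- rowsum(w, pbin)
    mass[as.integer(rownames(agg))] <- agg[, 1]
    map_bin <- which.max(mass)
    map <- grid$values[map_bin]

    eps_c <- eps_bins[map_bin]
    tilt <- perceived_tilt(bank$g[, map_bin])

    stm <- update_hml(stm, lik_bins[pbin])
    Wk <- mixture_weight(stm$sigma, config$chi2)
    t_now <- k * config$dk
    if (config$ltm_enabled) {
      ltm <- update_harmonious(ltm, map, eps_c, t_now)
    }

    last <- k * m + 1L
    rec$t[k] <- motion$t[last]
    rec$map[k] <- map
    rec$max_lik[k] <- max(lik_bins[pbin])
    rec$hml[k] <- stm$hml
    rec$sigma[k] <- stm$sigma
    rec$W[k] <- Wk
    rec$central_nis[k] <- eps_c
    rec$roll_true[k] <- prep$kin$roll[last]
    rec$roll_perceived[k] <- tilt[["roll"]]
    rec$g_true[k] <- motion$g_true[last]
    rec$ess[k] <- 1 / sum(w^2)
    if (length(ltm$values)) {
      rec$ltm_mass[k] <- length(ltm$values) / ltm$n_wind
      for (j in seq_along(levels)) {
        ltm_level_mass[k, j] <-
          sum(abs(ltm$values - levels[j]) <= 0.05) / ltm$n_wind
      }
    }
    if (keep_particles) {
      P[, k] <- x
      Wt[, k] <- w
    }
    if (keep_posterior) Post[, k] <- mass

    parents <- x[with_stream(
      rs_stream,
      resample_indices(w, config$n_particles, config$resample)
    )]
    x <- with_stream(tr_stream, sample_transitions(parents, stm, ltm, tm))
  }

  steps <- tibble::as_tibble(rec)
  names(steps)[names(steps) == "map"] <- "map_estimate"
  steps <- dplyr::bind_cols(steps, tibble::as_tibble(ltm_level_mass))
  structure(
    list(
      steps = steps,
      particles = if (keep_particles) P,
      weights = if (keep_particles) Wt,
      posterior = if (keep_posterior) Post,
      ltm_final = ltm,
      config = config, seed = seed, seeds = seeds,
      schedule = schedule, n_steps = n_steps
    ),
    class = "grav_sim"
  )
}

#' @export
print.grav_sim <- function(x, ...) {
  cat(sprintf(
    "<grav_sim> %d filter steps (dk = %g), N_s = %d, LTM %s, seed %s\n",
    x$n_steps, x$config$dk, x$config$n_particles,
    if (x$config$ltm_enabled) "on" else "off", format(x$seed)
  ))
  cat(sprintf(
    "  final MAP %.2f g (true %.2f g)\n",
    tail(x$steps$map_estimate, 1), tail(x$steps$g_true, 1)
  ))
  invisible(x)
}

#' Exhaustive grid Bayes filter (sampling-free reference)
#'
#' Propagates the full posterior over a (small) gravity grid through the
#' exact transition density and the same likelihoods as the particle
#' filter, with no Monte Carlo sampling. As `N_s` grows, the particle
#' filter's per-step posterior converges to this filter's; the comparison
#' is the standard correctness check for the sampling machinery.
#'
#' The jitter width and LTM weight depend on the history of maximum
#' *particle* likelihood, which the exact filter emulates by taking the
#' maximum likelihood over bins an `N_s`-particle ensemble would occupy
#' (predicted mass at least `1 / N_s`).
#'
#' @inheritParams simulate_adaptation
#' @param occupancy_floor Minimum predicted bin mass for a bin to count as
#'   occupied in the likelihood-history update (default `1 / n_particles`).
#' @return A list with `posterior` (bins x steps matrix), `map`, `t`,
#'   `hml`, `sigma`, `W` traces.
#' @export
grid_bayes_reference <- function(motion, config = engine_config(), seed = 1,
                                 occupancy_floor = 1 / config$n_particles) {
  stopifnot(inherits(config, "grav_config"))
  if (config$grid$n > 50) {
    abort("the exhaustive reference is restricted to grids of <= 50 bins.")
  }
  seeds <- derive_stream_seeds(seed)
  prep <- prepare_afference(motion, config, seeds[["noise"]])
  grid <- config$grid
  m <- config$substeps
  n_steps <- (nrow(motion) - 1L) %/% m

  u0 <- c(prep$kin$ux[1], prep$kin$uy[1], prep$kin$uz[1])
  bank <- new_observer_bank(grid$values, config$observer, u0)
  q <- numeric(grid$n)
  q[grid_bin(grid, grid_snap(grid, motion$g_true[1]))] <- 1

  logc <- log_likelihood_const(config$S)
  stm <- stm_state(
    hml = exp(logc), f = config$f, chi1 = config$chi1,
    c_jitter = config$c_jitter,
    sigma_min = config$sigma_min, sigma_max = config$sigma_max
  )
  ltm <- ltm_state(nu = config$nu, t_wind = config$t_wind, dk = config$dk)
  tm <- transition_model(chi2 = config$chi2, grid = grid)
  Sinv_chol <- chol(config$S)

  Post <- matrix(NA_real_, grid$n, n_steps)
  map <- hml <- sigma <- Wtr <- tvec <- numeric(n_steps)

  for (k in seq_len(n_steps)) {
    idx <- ((k - 1L) * m + 2L):(k * m + 1L)
    bank <- bank_advance(bank, prep$canal[, idx, drop = FALSE],
      prep$oto[, idx, drop = FALSE],
      dt = config$dt
    )
    z <- backsolve(Sinv_chol, bank$conflict$reduced, transpose = TRUE)
    eps_bins <- colSums(z^2)
    loglik_bins <- logc - eps_bins / 2
    lik_bins <- exp(loglik_bins)

    lw <- loglik_bins + log(q)
    lw[q == 0] <- -Inf
    post <- exp(lw - max(lw))
    post <- post / sum(post)
    Post[, k] <- post
    map_bin <- which.max(post)
    map[k] <- grid$values[map_bin]

    occupied <- q >= occupancy_floor
    if (!any(occupied)) occupied <- q > 0
    stm <- update_hml(stm, lik_bins[occupied])
    Wtr[k] <- mixture_weight(stm$sigma, config$chi2)
    hml[k] <- stm$hml
    sigma[k] <- stm$sigma
    tvec[k] <- motion$t[k * m + 1L]
    if (config$ltm_enabled) {
      ltm <- update_harmonious(ltm, map[k], eps_bins[map_bin], k * config$dk)
    }

    q <- numeric(grid$n)
    for (b in which(post > 0)) {
      q <- q + post[b] * transition_density(grid$values[b], stm, ltm, tm)
    }
    q <- q / sum(q)
  }
  list(posterior = Post, map = map, t = tvec, hml = hml, sigma = sigma, W = Wtr)
}
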