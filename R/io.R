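#' Load a scenario + engine configuration from YAML or JSON
#'
#' The file has two top-level blocks. `scenario` holds `motion` (fields
#' `type` = `"roll_tilt"`, `duration`, and optionally `dt`, `freq`,
#' `peak_velocity`) and `gravity`, a list of `{start, level}` segments.
#' `engine` may override any scalar argument of [engine_config()] plus
#' `S_sigma` (length-3 conflict standard deviations), `oto_weights`,
#' `observer` gain fields, and `grid` (`g_min`, `g_max`, `step`). Unknown
#' keys are rejected with the path to the offending field; all defaults are
#' materialized into the returned config so the output metadata echoes
#' every effective parameter.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `motion` (a `grav_motion` tibble) and
#'   `config` (a [engine_config()]).
#' @export
load_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(raw, c("scenario", "engine"), "")
  sc <- raw$scenario
  if (is.null(sc)) abort("missing `scenario` block.")
  check_keys(sc, c("motion", "gravity"), "scenario")
  mo <- sc$motion
  if (is.null(mo)) abort("missing `scenario.motion` block.")
  check_keys(
    mo, c("type", "duration", "dt", "freq", "peak_velocity"),
    "scenario.motion"
  )
  if (!identical(mo$type, "roll_tilt")) {
    abort("scenario.motion.type: only \"roll_tilt\" is supported.")
  }
  if (is.null(mo$duration) || mo$duration <= 0) {
    abort("scenario.motion.duration must be a positive number.")
  }

  en <- raw$engine %||% list()
  allowed_engine <- c(
    "n_particles", "noise_power", "f", "chi1", "c_jitter",
    "sigma_min", "sigma_max", "chi2", "nu", "t_wind", "dt", "dk",
    "ltm_enabled", "resample", "S_sigma", "oto_weights", "grid",
    "k_omega", "k_f", "k_fomega", "k_a", "tau_canal", "tau_a"
  )
  check_keys(en, allowed_engine, "engine")
  if (!is.null(en$n_particles) && en$n_particles < 1) {
    abort("engine.n_particles must be >= 1.")
  }
  if (!is.null(en$grid)) check_keys(en$grid, c("g_min", "g_max", "step"), "engine.grid")

  dt <- en$dt %||% mo$dt %||% 0.05
  grid_args <- en$grid %||% list()
  grid <- do.call(gravity_grid, grid_args)
  obs_args <- en[intersect(
    names(en),
    c("k_omega", "k_f", "k_fomega", "k_a", "tau_canal", "tau_a", "oto_weights")
  )]
  if (is.null(obs_args$oto_weights)) obs_args$oto_weights <- c(1, 0.4, 1)
  observer <- do.call(observer_params, c(obs_args, list(dt = dt)))
  S <- if (is.null(en$S_sigma)) noise_covariance() else noise_covariance(en$S_sigma)

  cfg_args <- en[intersect(names(en), c(
    "n_particles", "noise_power", "f", "chi1", "c_jitter", "sigma_min",
    "sigma_max", "chi2", "nu", "t_wind", "dk", "ltm_enabled", "resample"
  ))]
  config <- do.call(engine_config, c(
    cfg_args,
    list(grid = grid, observer = observer, S = S, dt = dt)
  ))

  motion <- roll_tilt_motion(
    duration = mo$duration, dt = dt,
    freq = mo$freq %||% 1, peak_velocity = mo$peak_velocity %||% 10
  )
  if (!is.null(sc$gravity)) {
    seg <- if (is.data.frame(sc$gravity)) {
      sc$gravity
    } else {
      do.call(rbind, lapply(sc$gravity, function(s) {
        check_keys(s, c("start", "level"), "scenario.gravity[]")
        data.frame(start = s$start, level = s$level)
      }))
    }
    motion <- set_gravity_schedule(motion, seg)
  }
  list(motion = motion, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf(
      "unknown field%s %s in `%s`.",
      if (length(extra) > 1) "s" else "",
      paste0("`", extra, "`", collapse = ", "),
      if (nzchar(where)) where else "<top level>"
    ))
  }
  invisible(x)
}

#' Write simulation results to a directory
#'
#' Writes `steps.csv` (one row per filter step), `metadata.json` (every
#' effective engine parameter, the seed, the derived stream seeds and the
#' gravity schedule) and, when particle traces were kept, `particles.csv`
#' (long format: step, particle, x, w). The written pair round-trips
#' through [read_results()].
#'
#' @param sim A `grav_sim` from [simulate_adaptation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(sim, dir) {
  stopifnot(inherits(sim, "grav_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$steps, file.path(dir, "steps.csv"), row.names = FALSE)
  cfg <- sim$config
  meta <- list(
    seed = sim$seed, stream_seeds = as.list(sim$seeds),
    n_particles = cfg$n_particles,
    grid = cfg$grid[c("g_min", "g_max", "step")],
    observer = cfg$observer[c(
      "k_omega", "k_f", "k_fomega", "k_a", "tau_canal", "tau_a",
      "oto_weights", "dt"
    )],
    S = as.vector(unclass(cfg$S)),
    noise_power = cfg$noise_power,
    f = cfg$f, chi1 = cfg$chi1, c_jitter = cfg$c_jitter,
    sigma_min = cfg$sigma_min, sigma_max = cfg$sigma_max,
    chi2 = cfg$chi2, nu = cfg$nu, t_wind = cfg$t_wind,
    dt = cfg$dt, dk = cfg$dk, ltm_enabled = cfg$ltm_enabled,
    resample = cfg$resample,
    schedule = sim$schedule
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(sim$particles)) {
    long <- tibble::tibble(
      step = rep(seq_len(ncol(sim$particles)), each = nrow(sim$particles)),
      particle = rep(seq_len(nrow(sim$particles)), ncol(sim$particles)),
      x = as.vector(sim$particles),
      w = as.vector(sim$weights)
    )
    utils::write.csv(long, file.path(dir, "particles.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read back written simulation results
#'
#' @param dir Directory written by [write_results()].
#' @return A list with `steps` (tibble), `metadata` (list) and, if present,
#'   `particles` (tibble).
#' @export
read_results <- function(dir) {
  out <- list(
    steps = tibble::as_tibble(
      utils::read.csv(file.path(dir, "steps.csv"))
    ),
    metadata = jsonlite::read_json(
      file.path(dir, "metadata.json"),
      simplifyVector = TRUE
    )
  )
  pfile <- file.path(dir, "particles.csv")
  if (file.exists(pfile)) {
    out$particles <- tibble::as_tibble(utils::read.csv(pfile))
  }
  out
}
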