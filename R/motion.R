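#' Build a head-motion profile
#'
#' A head-motion profile is a tibble with one row per simulation step and
#' columns `t` (model seconds), `wx, wy, wz` (head-frame angular velocity,
#' rad/s), `ax, ay, az` (inertial linear acceleration, g units, head frame)
#' and `g_true` (true gravity magnitude, g units). The simulation step
#' `dt` and the initial world-to-head orientation quaternion `q0` are
#' carried as attributes. Head frame: x forward, y left, z up; world z up;
#' the gravity vector points down.
#'
#' @param t Uniform time grid (model seconds).
#' @param omega n-by-3 matrix (or data frame) of angular velocity.
#' @param accel n-by-3 matrix of inertial acceleration.
#' @param g_true True gravity magnitude per step (recycled if scalar).
#' @param q0 Initial orientation quaternion `(w, x, y, z)`, unit norm.
#' @return A tibble of class `grav_motion`.
#' @export
head_motion <- function(t, omega, accel, g_true = 1, q0 = c(1, 0, 0, 0)) {
  omega <- as.matrix(omega)
  accel <- as.matrix(accel)
  stopifnot(ncol(omega) == 3, ncol(accel) == 3)
  n <- length(t)
  stopifnot(nrow(omega) == n, nrow(accel) == n)
  g_true <- rep_len(g_true, n)
  out <- tibble::tibble(
    t = as.numeric(t),
    wx = omega[, 1], wy = omega[, 2], wz = omega[, 3],
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    g_true = as.numeric(g_true)
  )
  dt <- if (n > 1) t[2] - t[1] else NA_real_
  attr(out, "dt") <- dt
  attr(out, "q0") <- q0
  class(out) <- c("grav_motion", class(out))
  validate_head_motion(out)
}

validate_head_motion <- function(motion) {
  n <- nrow(motion)
  if (n < 2) abort("motion must have at least 2 steps.")
  dt <- attr(motion, "dt")
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be positive.")
  if (max(abs(diff(motion$t) - dt)) > 1e-9 * max(1, dt)) {
    abort("non-uniform time grid.")
  }
  num <- as.matrix(motion[, c("wx", "wy", "wz", "ax", "ay", "az", "g_true")])
  if (any(!is.finite(num))) abort("motion contains non-finite values.")
  if (any(motion$g_true < 0)) abort("`g_true` must be non-negative.")
  q0 <- attr(motion, "q0")
  if (length(q0) != 4 || abs(sqrt(sum(q0^2)) - 1) > 1e-9) {
    abort("`q0` must be a unit quaternion (within 1e-9).")
  }
  motion
}

#' Passive sinusoidal roll-tilt stimulus
#'
#' The canonical stimulus: passive sinusoidal roll tilt at angular frequency
#' `freq` with peak angular velocity `peak_velocity`. Roll angular velocity
#' is `wx(t) = peak_velocity * cos(freq * t)`, so the implied peak roll
#' displacement is `peak_velocity / freq` (10 deg for the defaults). There
#' is no inertial linear acceleration; the otoliths see only the rotating
#' gravity vector.
#'
#' @param duration Total duration (model seconds).
#' @param dt Simulation step (model seconds).
#' @param freq Angular frequency (rad/s); default 1 rad/s (0.159 Hz).
#' @param peak_velocity Peak roll angular velocity (deg/s).
#' @param g_true True gravity magnitude (scalar here; use
#'   [set_gravity_schedule()] for transitions).
#' @return A `grav_motion` tibble.
#' @export
#' @examples
#' m <- roll_tilt_motion(duration = 20)
#' range(m$wx) * 180 / pi # +/- 10 deg/s
roll_tilt_motion <- function(duration, dt = 0.05, freq = 1,
                             peak_velocity = 10, g_true = 1) {
  stopifnot(duration > 0, dt > 0, freq > 0, peak_velocity >= 0)
  if (dt > pi / (10 * freq)) {
    abort("`dt` undersamples the stimulus: need dt <= pi / (10 * freq).")
  }
  t <- seq(0, duration, by = dt)
  w_peak <- peak_velocity * pi / 180
  omega <- cbind(w_peak * cos(freq * t), 0, 0)
  accel <- matrix(0, length(t), 3)
  head_motion(t, omega, accel, g_true = g_true)
}

#' Apply a piecewise-constant gravity schedule
#'
#' Overwrite a motion profile's `g_true` column with a piecewise-constant
#' schedule. Transitions are instantaneous steps, as when a centrifuge (or
#' vehicle) changes its effective gravity level abruptly.
#'
#' @param motion A `grav_motion` tibble.
#' @param segments A data frame with columns `start` (model seconds,
#'   strictly increasing, first must be 0) and `level` (g units, `>= 0`).
#' @return The motion with `g_true` replaced; segment metadata is stored in
#'   attribute `"schedule"`.
#' @export
#' @examples
#' m <- roll_tilt_motion(duration = 40) |>
#'   set_gravity_schedule(data.frame(start = c(0, 20), level = c(1, 4)))
set_gravity_schedule <- function(motion, segments) {
  stopifnot(is.data.frame(segments), all(c("start", "level") %in% names(segments)))
  s <- segments[order(segments$start), , drop = FALSE]
  if (any(duplicated(s$start)) || any(diff(s$start) <= 0)) {
    abort("segment start times must be strictly increasing (no overlaps).")
  }
  if (s$start[1] != 0) abort("the first segment must start at time 0.")
  if (any(s$level < 0)) abort("gravity levels must be non-negative.")
  if (any(s$start >= max(motion$t))) {
    abort("segment start beyond the motion duration.")
  }
  idx <- findInterval(motion$t, s$start)
  motion$g_true <- s$level[idx]
  attr(motion, "schedule") <- tibble::as_tibble(s[, c("start", "level")])
  motion
}

#' Canonical gravity-transition scenarios
#'
#' Named roll-tilt scenarios covering the standard simulation set: a single
#' hyper-gravity step (`step_1to4`), the same step run long enough to watch
#' memory of the departed level age out (`lifecycle`), and four
#' transition histories used for readaptation comparisons --
#' `relearn_4141` (1 -> 4 -> 1 -> 4 g: both later transitions return to
#' learned levels), `prolonged_14` (a long 1 g stint then 4 g),
#' `novel_1214` (1 -> 2 -> 1 -> 4 g: the final 4 g is novel) and
#' `novel_1h14` (1 -> 0.5 -> 1 -> 4 g: hypo-gravity first, then novel
#' hyper-gravity). `tilt_probe` is the first 1 -> 4 g transition with the
#' roll-tilt perception probes used to demonstrate the G-excess illusion.
#' All scenarios start at 1 Earth gravity.
#'
#' @param segment Duration of one schedule segment (model seconds). The
#'   default (100) is several times the observed 1 -> 4 g adaptation time
#'   under default parameters, so a learned state forms before the next
#'   transition.
#' @param dt Simulation step (model seconds).
#' @param freq,peak_velocity Stimulus parameters, see [roll_tilt_motion()].
#' @return Named list of `grav_motion` tibbles; each carries its schedule in
#'   attribute `"schedule"`.
#' @export
canonical_scenarios <- function(segment = 100, dt = 0.05, freq = 1,
                                peak_velocity = 10) {
  levels <- list(
    step_1to4 = c(1, 4),
    lifecycle = c(1, 4),
    relearn_4141 = c(1, 4, 1, 4),
    prolonged_14 = c(1, 1, 4),
    novel_1214 = c(1, 2, 1, 4),
    novel_1h14 = c(1, 0.5, 1, 4),
    tilt_probe = c(1, 4)
  )
  durations <- list(
    step_1to4 = c(0.5, 1) * segment,
    lifecycle = c(1, 3.5) * segment,
    relearn_4141 = rep(segment, 4),
    prolonged_14 = rep(segment, 3),
    novel_1214 = rep(segment, 4),
    novel_1h14 = rep(segment, 4),
    tilt_probe = c(1, 1) * segment
  )
  out <- lapply(names(levels), function(nm) {
    lv <- levels[[nm]]
    du <- durations[[nm]]
    starts <- cumsum(c(0, head(du, -1)))
    roll_tilt_motion(
      duration = sum(du), dt = dt, freq = freq,
      peak_velocity = peak_velocity
    ) |>
      set_gravity_schedule(data.frame(start = starts, level = lv))
  })
  setNames(out, names(levels))
}
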