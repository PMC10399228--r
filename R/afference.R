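#' Observer model parameters
#'
#' Gains and time constants of the vestibular observer. The observer
#' compares actual afference with the afference its internal sensor models
#' expect, and feeds the resulting conflicts back onto its perceptual
#' states:
#' * `k_omega` -- angular-velocity correction from the canal conflict;
#' * `k_f` -- rotation of the perceived gravity direction from the
#'   GIF-direction conflict;
#' * `k_fomega` -- angular-velocity correction from the GIF-direction
#'   conflict (lets sustained tilt mis-alignment imply rotation);
#' * `k_a` -- linear-acceleration correction from the acceleration
#'   conflict (applied as a positive corrective gain);
#' * `tau_canal` -- time constant of the canal high-pass dynamics (s);
#' * `tau_a` -- leak time constant of the acceleration estimate (s);
#' * `oto_weights` -- per-axis differential weighting of the otolith
#'   conflict components (applied inside both the acceleration and the
#'   GIF-direction conflicts). `(1, 1, 1)` reproduces the unweighted
#'   observer, which perceives tilt veridically at every gravity magnitude;
#'   down-weighting the interaural (y) component makes unexplained otolith
#'   shear resolve into tilt rather than acceleration, producing the
#'   G-excess tilt overestimation seen in unadapted hyper-gravity.
#'
#' Defaults are literature-inspired, not fitted values; all simulations run
#' in unitless "model seconds".
#'
#' @param k_omega,k_f,k_fomega,k_a Feedback gains (dimensionless).
#' @param tau_canal,tau_a Time constants (model seconds, `> 0`).
#' @param oto_weights Length-3 non-negative weight vector.
#' @param dt Integration step (model seconds).
#' @return A list of class `grav_observer_params`.
#' @export
observer_params <- function(k_omega = 8, k_f = 4, k_fomega = 8, k_a = 4,
                            tau_canal = 5.7, tau_a = 1,
                            oto_weights = c(1, 1, 1), dt = 0.05) {
  stopifnot(
    tau_canal > 0, tau_a > 0, dt > 0,
    length(oto_weights) == 3, all(oto_weights >= 0)
  )
  if (dt >= tau_canal / 2) {
    abort("`dt` must be < tau_canal / 2 for a stable canal discretization.")
  }
  structure(
    list(
      k_omega = k_omega, k_f = k_f, k_fomega = k_fomega, k_a = k_a,
      tau_canal = tau_canal, tau_a = tau_a,
      oto_weights = as.numeric(oto_weights), dt = dt
    ),
    class = "grav_observer_params"
  )
}

# Bilinear (Tustin) discretization of the canal high-pass
# H(s) = tau s / (tau s + 1):
#   y[k] = a * y[k-1] + b * (u[k] - u[k-1]).
canal_coefs <- function(tau, dt) {
  list(a = (2 * tau - dt) / (2 * tau + dt), b = 2 * tau / (2 * tau + dt))
}

#' Simulate vestibular afference from a truth trajectory
#'
#' The semicircular canals transduce angular velocity through first-order
#' high-pass dynamics (transfer function `tau s / (tau s + 1)`, discretized
#' by the bilinear transform at `dt`); the otoliths transduce the specific
#' force with identity dynamics.
#'
#' @param kin A `grav_kinematics` tibble from [head_kinematics()].
#' @param params A [observer_params()].
#' @return The input tibble with added columns `canal_x/y/z` (rad/s) and
#'   `oto_x/y/z` (g units); attribute `"noisy"` is `FALSE`.
#' @export
vestibular_afference <- function(kin, params = observer_params()) {
  stopifnot(inherits(kin, "grav_kinematics"))
  dt <- attr(kin, "dt")
  cf <- canal_coefs(params$tau_canal, dt)
  hp <- function(u) {
    y <- stats::filter(cf$b * diff(c(0, u)), cf$a, method = "recursive")
    as.numeric(y)
  }
  kin$canal_x <- hp(kin$wx)
  kin$canal_y <- hp(kin$wy)
  kin$canal_z <- hp(kin$wz)
  kin$oto_x <- kin$fx
  kin$oto_y <- kin$fy
  kin$oto_z <- kin$fz
  attr(kin, "noisy") <- FALSE
  class(kin) <- unique(c("grav_afference", class(kin)))
  kin
}

#' Add white sensory noise to afference
#'
#' Adds independent zero-mean Gaussian noise to every afferent channel and
#' sample with variance `noise_power / dt` (noise power is the height of
#' the power spectral density of the added white noise, so trajectories are
#' `dt`-invariant in distribution). Deterministic given `seed`.
#'
#' @param aff A `grav_afference` tibble from [vestibular_afference()].
#' @param noise_power Noise power ((signal units)^2 * s, `>= 0`); the
#'   canonical value is `1e-8`.
#' @param seed Integer seed for the noise stream.
#' @return The tibble with noise added to the `canal_*` and `oto_*`
#'   columns; attribute `"noisy"` is `TRUE` unless `noise_power` is 0.
#' @export
add_sensory_noise <- function(aff, noise_power = 1e-8, seed = 1) {
  stopifnot(inherits(aff, "grav_afference"), noise_power >= 0)
  if (noise_power == 0) {
    return(aff)
  }
  dt <- attr(aff, "dt")
  sd <- sqrt(noise_power / dt)
  cols <- c("canal_x", "canal_y", "canal_z", "oto_x", "oto_y", "oto_z")
  stream <- new_rng_stream(seed)
  noise <- with_stream(stream, matrix(rnorm(nrow(aff) * 6, sd = sd), ncol = 6))
  for (j in seq_along(cols)) aff[[cols[j]]] <- aff[[cols[j]]] + noise[, j]
  attr(aff, "noisy") <- TRUE
  aff
}
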