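# Observer bank internals.
#
# The bank holds one magnitude-constrained observer per gravity-grid value,
# advanced in lockstep on the shared (noisy) afference. State is stored as
# 3-by-N matrices; each column is one conditioned observer. This is
# mathematically equivalent to re-running each conditioned observer from
# t = 0 on the shared afference, without the re-simulation cost.

new_observer_bank <- function(x_values, params, u0 = c(0, 0, 1)) {
  n <- length(x_values)
  u0 <- u0 / sqrt(sum(u0^2))
  list(
    x = x_values,
    g = outer(u0, x_values), # perceived gravity up-vector, |col j| = x_j
    a = matrix(0, 3, n), # perceived linear acceleration (g units)
    w = matrix(0, 3, n), # perceived angular velocity (rad/s)
    can_in = matrix(0, 3, n), # internal canal model: previous input
    can_out = matrix(0, 3, n), # internal canal model: previous output
    params = params
  )
}

# Advance the whole bank over a block of afference samples (3 x m
# matrices). Returns the bank plus the conflict matrices of the final
# sub-step. One vectorized Euler step per sample:
#   expected canal   = internal high-pass applied to omega_hat
#   e_omega          = canal afference - expected canal
#   f_hat            = a_hat + g_hat (up-vector convention)
#   e_a              = oto_weights * (oto afference - f_hat)
#   e_f              = oto_weights * (unit(oto) x unit(f_hat))
#   omega_hat        += dt (k_omega e_omega + k_fomega e_f)
#   g_hat            <- rotate(g_hat, dt (-omega_hat + k_f e_f)), then
#                       rescaled to the conditioning magnitude
#   a_hat            += dt (k_a e_a - a_hat / tau_a)
bank_advance <- function(bank, canal, oto, dt) {
  p <- bank$params
  cf <- canal_coefs(p$tau_canal, dt)
  wts <- p$oto_weights
  g <- bank$g
  a <- bank$a
  w <- bank$w
  can_in <- bank$can_in
  can_out <- bank$can_out
  x <- bank$x
  m <- ncol(canal)
  e_a <- e_f <- e_w <- NULL
  for (i in seq_len(m)) {
    yc <- canal[, i]
    yo <- oto[, i]
    # internal canal model (same bilinear discretization as the sensor)
    can_out <- cf$a * can_out + cf$b * (w - can_in)
    can_in <- w
    e_w <- yc - can_out
    f_hat <- a + g
    e_a <- wts * (yo - f_hat)
    nf <- sqrt(colSums(f_hat^2))
    no <- sqrt(sum(yo^2))
    if (no < 1e-9) {
      e_f <- matrix(0, 3, length(x))
    } else {
      od <- yo / no
      fd <- f_hat / rep(pmax(nf, 1e-300), each = 3)
      e_f <- wts * rbind(
        od[2] * fd[3, ] - od[3] * fd[2, ],
        od[3] * fd[1, ] - od[1] * fd[3, ],
        od[1] * fd[2, ] - od[2] * fd[1, ]
      )
      e_f[, nf < 1e-9] <- 0
    }
    # e_f = unit(actual) x unit(expected). Both feedback paths must rotate
    # the expected GIF toward the measured one: through the angular-velocity
    # estimate (g_hat is rotated by -omega_hat, so omega_hat gains +e_f) and
    # directly on g_hat (which therefore gains -e_f). Gains are positive
    # corrective magnitudes.
    w <- w + dt * (p$k_omega * e_w + p$k_fomega * e_f)
    r <- dt * (-p$k_f * e_f - w)
    g <- rotate_columns(g, r)
    gn <- sqrt(colSums(g^2))
    g <- g * rep(ifelse(gn > 0, x / gn, 0), each = 3)
    a <- a + dt * (p$k_a * e_a - a / p$tau_a)
  }
  bank$g <- g
  bank$a <- a
  bank$w <- w
  bank$can_in <- can_in
  bank$can_out <- can_out
  bank$conflict <- list(
    e_a = e_a, e_f = e_f, e_omega = e_w,
    reduced = rbind(
      sqrt(colSums(e_a^2)), sqrt(colSums(e_f^2)), sqrt(colSums(e_w^2))
    )
  )
  bank
}

# Rodrigues rotation of each column of `v` (3 x N) by the corresponding
# rotation vector in `r` (3 x N).
rotate_columns <- function(v, r) {
  th <- sqrt(colSums(r^2))
  safe <- pmax(th, 1e-300)
  k <- r / rep(safe, each = 3)
  kxv <- rbind(
    k[2, ] * v[3, ] - k[3, ] * v[2, ],
    k[3, ] * v[1, ] - k[1, ] * v[3, ],
    k[1, ] * v[2, ] - k[2, ] * v[1, ]
  )
  kdv <- colSums(k * v)
  out <- v * rep(cos(th), each = 3) +
    kxv * rep(sin(th), each = 3) +
    k * rep(kdv * (1 - cos(th)), each = 3)
  tiny <- th < 1e-12
  if (any(tiny)) out[, tiny] <- v[, tiny] + kxv[, tiny] * rep(th[tiny], each = 3)
  out
}

#' Construct a single-observer perception state
#'
#' The perceptual state of one observer conditioned on a gravity-magnitude
#' hypothesis: perceived gravity up-vector `g_hat` (magnitude pinned to the
#' hypothesis), perceived linear acceleration `a_hat`, perceived angular
#' velocity `omega_hat`, and the internal canal-model filter state.
#'
#' @param x_hyp Conditioning gravity magnitude (g units, `>= 0`).
#' @param u0 Initial perceived up direction (unit vector, head frame).
#' @return A list of class `grav_perception`.
#' @export
perception_state <- function(x_hyp, u0 = c(0, 0, 1)) {
  stopifnot(x_hyp >= 0)
  u0 <- u0 / sqrt(sum(u0^2))
  structure(
    list(
      g_hat = u0 * x_hyp, a_hat = c(0, 0, 0), omega_hat = c(0, 0, 0),
      canal_in = c(0, 0, 0), canal_out = c(0, 0, 0), x_hyp = x_hyp
    ),
    class = "grav_perception"
  )
}

#' Advance one observer by one step
#'
#' Single-hypothesis form of the observer update (see [observer_params()]
#' for the feedback structure). The perceived gravity vector is re-scaled to
#' the conditioning magnitude after every step, so the hypothesis acts as a
#' hard constraint and all disagreement is routed into the conflict signals.
#'
#' @param state A [perception_state()].
#' @param y One-step afference: a list with elements `canal` and `oto`
#'   (3-vectors).
#' @param x_hyp Gravity-magnitude hypothesis (g units, `>= 0`); must match
#'   the magnitude of `state$g_hat`.
#' @param params A [observer_params()].
#' @return A list with elements `state` (updated `grav_perception`) and
#'   `conflict` (list with `e_a`, `e_f`, `e_omega` and `reduced`, the vector
#'   of their norms).
#' @export
observer_step <- function(state, y, x_hyp, params = observer_params()) {
  if (x_hyp < 0) abort("`x_hyp` must be non-negative.")
  if (abs(sqrt(sum(state$g_hat^2)) - x_hyp) > 1e-6) {
    abort("`state$g_hat` magnitude does not match `x_hyp`.")
  }
  if (any(!is.finite(c(y$canal, y$oto)))) abort("afference must be finite.")
  bank <- list(
    x = x_hyp,
    g = matrix(state$g_hat, 3, 1),
    a = matrix(state$a_hat, 3, 1),
    w = matrix(state$omega_hat, 3, 1),
    can_in = matrix(state$canal_in, 3, 1),
    can_out = matrix(state$canal_out, 3, 1),
    params = params
  )
  bank <- bank_advance(
    bank,
    matrix(y$canal, 3, 1), matrix(y$oto, 3, 1),
    dt = params$dt
  )
  state$g_hat <- bank$g[, 1]
  state$a_hat <- bank$a[, 1]
  state$omega_hat <- bank$w[, 1]
  state$canal_in <- bank$can_in[, 1]
  state$canal_out <- bank$can_out[, 1]
  conflict <- lapply(bank$conflict, function(mat) mat[, 1])
  list(state = state, conflict = conflict)
}

#' Perceived tilt angles from a gravity vector
#'
#' Roll is `atan2(g_y, g_z)` and pitch `atan2(g_x, g_z)` (degrees), using
#' the perceived up-vector; both are invariant to rescaling, so tilt
#' perception does not depend on the hypothesised gravity magnitude.
#'
#' @param g_hat Perceived gravity up-vector (3-vector, any positive norm).
#' @return Named numeric vector `c(roll, pitch)` in degrees.
#' @export
perceived_tilt <- function(g_hat) {
  if (sqrt(sum(g_hat^2)) == 0) abort("tilt undefined for |g_hat| = 0.")
  c(
    roll = atan2(g_hat[2], g_hat[3]) * 180 / pi,
    pitch = atan2(g_hat[1], g_hat[3]) * 180 / pi
  )
}
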