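# Quaternion helpers. Quaternions are (w, x, y, z); `Q` maps head frame to
# world frame, so a world vector expressed in head coordinates is
# rotate(conjugate(Q), v).

quat_mult <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_from_rotvec <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) {
    c(1, r / 2)
  } else {
    c(cos(th / 2), sin(th / 2) * r / th)
  }
}

#' Integrate head kinematics (truth trajectory)
#'
#' Integrate the orientation quaternion from the angular-velocity history,
#' and derive the gravity vector in head coordinates and the otolith-sensed
#' specific force at every step. The quaternion is advanced by the exact
#' rotation of `omega * dt` each step and renormalized, so drift stays at
#' rounding level. Specific force is `accel - g_head` where
#' `g_head = R' (0, 0, -g_true)` (world z up): a stationary upright head in
#' 1 g senses `(0, 0, +1)` g. Positive roll rotation (about +x) tilts the
#' sensed up-vector toward +y, so the roll angle read back by
#' [perceived_tilt()] matches the integral of `wx`.
#'
#' @param motion A `grav_motion` tibble from [head_motion()] or
#'   [roll_tilt_motion()].
#' @return The motion tibble with added columns `qw,qx,qy,qz` (head-to-world
#'   quaternion), `ux,uy,uz` (unit up-vector in head frame), `fx,fy,fz`
#'   (specific force, g units) and `roll`, `pitch` (deg).
#' @export
#' @examples
#' k <- head_kinematics(roll_tilt_motion(duration = 10))
#' max(abs(k$roll)) # ~10 deg peak roll
head_kinematics <- function(motion) {
  validate_head_motion(motion)
  n <- nrow(motion)
  dt <- attr(motion, "dt")
  omega <- rbind(motion$wx, motion$wy, motion$wz)
  accel <- rbind(motion$ax, motion$ay, motion$az)

  Qs <- matrix(0, 4, n)
  U <- matrix(0, 3, n)
  Q <- attr(motion, "q0")
  for (i in seq_len(n)) {
    Qs[, i] <- Q
    qc <- c(Q[1], -Q[2:4])
    p <- quat_mult(quat_mult(qc, c(0, 0, 0, 1)), Q)
    U[, i] <- p[2:4]
    if (i < n) {
      # trapezoidal sampling of the body rate keeps the integrated angle
      # second-order accurate (a left-rule step biases a 1 rad/s sinusoid
      # by ~dt/2 of phase, visible as a spurious mean roll)
      Q <- quat_mult(Q, quat_from_rotvec((omega[, i] + omega[, i + 1]) / 2 * dt))
      Q <- Q / sqrt(sum(Q^2))
    }
  }
  # specific force f = accel - g_head; g_head = -g_true * up
  f <- accel + U * rep(motion$g_true, each = 3)

  motion$qw <- Qs[1, ]
  motion$qx <- Qs[2, ]
  motion$qy <- Qs[3, ]
  motion$qz <- Qs[4, ]
  motion$ux <- U[1, ]
  motion$uy <- U[2, ]
  motion$uz <- U[3, ]
  motion$fx <- f[1, ]
  motion$fy <- f[2, ]
  motion$fz <- f[3, ]
  motion$roll <- atan2(U[2, ], U[3, ]) * 180 / pi
  motion$pitch <- atan2(U[1, ], U[3, ]) * 180 / pi
  class(motion) <- unique(c("grav_kinematics", class(motion)))
  motion
}
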