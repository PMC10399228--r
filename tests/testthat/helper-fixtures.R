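# Shared fixtures: small, fast configurations built in code.

# Engine config on a reduced grid for fast filter tests (overridable).
small_config <- function(...) {
  args <- list(n_particles = 50, grid = gravity_grid(0.76, 1.25, 0.01))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(engine_config, args)
}

# Run a single observer on prepared afference, returning per-step perceived
# roll and the last conflict.
run_single_observer <- function(aff, x_hyp, params, n = nrow(aff)) {
  st <- perception_state(x_hyp)
  roll <- numeric(n)
  conflict <- NULL
  for (i in seq_len(n)) {
    r <- observer_step(
      st,
      list(
        canal = c(aff$canal_x[i], aff$canal_y[i], aff$canal_z[i]),
        oto = c(aff$oto_x[i], aff$oto_y[i], aff$oto_z[i])
      ),
      x_hyp, params
    )
    st <- r$state
    conflict <- r$conflict
    roll[i] <- perceived_tilt(st$g_hat)[["roll"]]
  }
  list(state = st, conflict = conflict, roll = roll)
}

# Stationary upright afference (no noise): canal 0, oto (0, 0, g).
stationary_afference <- function(g = 1, n = 200, dt = 0.05) {
  m <- roll_tilt_motion(duration = n * dt, dt = dt, peak_velocity = 0, g_true = g)
  vestibular_afference(head_kinematics(m), observer_params())
}

# Random positive-definite 3x3 covariance.
random_pd_cov <- function() {
  A <- matrix(rnorm(9), 3, 3)
  S <- A %*% t(A) + diag(0.1, 3)
  noise_covariance(S = (S + t(S)) / 2)
}
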