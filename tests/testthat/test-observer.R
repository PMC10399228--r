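test_that("a matched observer at rest is a fixed point with vanishing conflicts", {
  p <- observer_params()
  aff <- stationary_afference(g = 1, n = 200)
  r <- run_single_observer(aff, x_hyp = 1, params = p)
  expect_lt(max(r$conflict$reduced), 1e-9)
  expect_equal(r$state$g_hat, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(r$state$a_hat, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(r$state$omega_hat, c(0, 0, 0), tolerance = 1e-9)
})

test_that("the gravity-magnitude constraint holds after every step", {
  p <- observer_params(oto_weights = c(1, 0.4, 1))
  m <- roll_tilt_motion(duration = 10, g_true = 4)
  aff <- vestibular_afference(head_kinematics(m), p)
  st <- perception_state(1.7)
  for (i in seq_len(nrow(aff))) {
    r <- observer_step(
      st,
      list(
        canal = c(aff$canal_x[i], aff$canal_y[i], aff$canal_z[i]),
        oto = c(aff$oto_x[i], aff$oto_y[i], aff$oto_z[i])
      ),
      1.7, p
    )
    st <- r$state
    expect_equal(sqrt(sum(st$g_hat^2)), 1.7, tolerance = 1e-9)
  }
})

test_that("zero canal afference with k_fomega = 0 leaves omega_hat at zero", {
  p <- observer_params(k_fomega = 0)
  aff <- stationary_afference(g = 2, n = 100)
  r <- run_single_observer(aff, x_hyp = 1, params = p) # mismatched on purpose
  expect_equal(r$state$omega_hat, c(0, 0, 0))
})

test_that("steady conflict is zero when matched and grows with the hypothesis mismatch", {
  p <- observer_params()
  S <- noise_covariance()
  aff <- stationary_afference(g = 1, n = 600)
  eps <- vapply(c(1, 1.5, 2, 3, 4), function(xh) {
    nis(run_single_observer(aff, xh, p)$conflict$reduced, S)
  }, numeric(1))
  expect_lt(eps[1], 1e-18)
  expect_true(all(diff(eps) > 0))
})

test_that("scaling gravity and hypothesis together scales forces, not direction conflict", {
  p <- observer_params(oto_weights = c(1, 0.4, 1))
  m1 <- roll_tilt_motion(duration = 10, g_true = 1)
  m2 <- roll_tilt_motion(duration = 10, g_true = 2)
  a1 <- vestibular_afference(head_kinematics(m1), p)
  a2 <- vestibular_afference(head_kinematics(m2), p)
  r1 <- run_single_observer(a1, x_hyp = 1, params = p)
  r2 <- run_single_observer(a2, x_hyp = 2, params = p)
  expect_equal(r2$conflict$e_a, 2 * r1$conflict$e_a, tolerance = 1e-9)
  expect_equal(r2$conflict$e_f, r1$conflict$e_f, tolerance = 1e-9)
  expect_equal(r2$state$a_hat, 2 * r1$state$a_hat, tolerance = 1e-9)
})

test_that("tilt extraction reads roll/pitch from the up-vector, scale-free", {
  expect_equal(perceived_tilt(c(0, 0, 1)), c(roll = 0, pitch = 0))
  expect_equal(perceived_tilt(c(0, sin(10 * pi / 180), cos(10 * pi / 180)))[["roll"]],
    10,
    tolerance = 1e-12
  )
  g <- c(0.1, 0.3, 0.9)
  expect_equal(perceived_tilt(g), perceived_tilt(4 * g))
  expect_error(perceived_tilt(c(0, 0, 0)), "undefined")
})

test_that("unadapted hyper-gravity overestimates roll tilt; adapted does not", {
  # the G-excess pattern: observer conditioned on 1 g in 4 g truth
  # overestimates roll; conditioned on 4 g it is veridical within 5%.
  p <- observer_params(oto_weights = c(1, 0.4, 1))
  m <- roll_tilt_motion(duration = 60, g_true = 4)
  k <- head_kinematics(m)
  aff <- vestibular_afference(k, p)
  sel <- aff$t > 40
  peak_true <- max(abs(k$roll[sel]))

  r_un <- run_single_observer(aff, x_hyp = 1, params = p)
  expect_gt(max(abs(r_un$roll[sel])) / peak_true, 1.2)

  r_ad <- run_single_observer(aff, x_hyp = 4, params = p)
  expect_equal(max(abs(r_ad$roll[sel])) / peak_true, 1, tolerance = 0.05)

  # down-weighting the interaural conflict strengthens the overestimation
  # relative to the uniformly weighted observer (whose static equilibrium
  # is veridical; its residual overestimation is purely dynamic)
  p_u <- observer_params(oto_weights = c(1, 1, 1))
  aff_u <- vestibular_afference(k, p_u)
  r_u <- run_single_observer(aff_u, x_hyp = 1, params = p_u)
  expect_gt(
    max(abs(r_un$roll[sel])) / peak_true,
    max(abs(r_u$roll[sel])) / peak_true + 0.2
  )
})

test_that("observer_step rejects invalid hypotheses and afference", {
  p <- observer_params()
  st <- perception_state(1)
  y <- list(canal = c(0, 0, 0), oto = c(0, 0, 1))
  expect_error(observer_step(st, y, -1, p), "non-negative")
  expect_error(
    observer_step(st, list(canal = c(NA, 0, 0), oto = c(0, 0, 1)), 1, p),
    "finite"
  )
  # x_hyp = 0 is permitted; degenerate direction conflict is zero
  st0 <- perception_state(0)
  r <- observer_step(st0, list(canal = c(0, 0, 0), oto = c(0, 0, 0)), 0, p)
  expect_equal(r$conflict$e_f, c(0, 0, 0))
})
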