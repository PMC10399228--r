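test_that("HML recursion is the stated exponentially weighted average", {
  stm <- stm_state(hml = 0.4, f = 0)
  expect_equal(update_hml(stm, c(0.1, 0.9, 0.3))$hml, 0.9) # f = 0: no memory
  stm <- stm_state(hml = 0.4, f = 1)
  expect_equal(update_hml(stm, 0.8)$hml, (0.4 + 0.8) / 2)
  # constant max likelihood is a fixed point
  stm <- stm_state(hml = 0, f = 0.8)
  for (i in 1:200) stm <- update_hml(stm, 0.7)
  expect_equal(stm$hml, 0.7, tolerance = 1e-9)
  expect_error(update_hml(stm, numeric(0)), "non-empty")
})

test_that("jitter width follows the clipped inverse-power law", {
  stm <- stm_state(hml = 1, chi1 = 1, c_jitter = 0.01, sigma_min = 1e-4, sigma_max = 1)
  expect_equal(stm$sigma, 0.01)
  stm$hml <- 2
  expect_equal(jitter_sigma(stm)$sigma, 0.005) # hml doubled -> sigma halved
  stm$hml <- 0
  expect_equal(jitter_sigma(stm)$sigma, 1) # vanished history -> max width
  stm$hml <- 1e12
  expect_equal(jitter_sigma(stm)$sigma, 1e-4) # clipped below
  # chi1 modulates sensitivity
  s2 <- stm_state(hml = 2, chi1 = 2, c_jitter = 0.01, sigma_min = 1e-6, sigma_max = 1)
  expect_equal(s2$sigma, 0.01 / 4)
})

test_that("STM density is a normalized grid Gaussian centred on the parent", {
  grid <- gravity_grid(0.05, 5, 0.01)
  for (sigma in c(0.005, 0.1, 2)) {
    d <- stm_density(1.3, sigma, grid)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_equal(grid$values[which.max(d)], 1.3)
  }
  # huge sigma: near-uniform over the grid
  d <- stm_density(2, 100 * (grid$g_max - grid$g_min), grid)
  expect_lt(max(d) / min(d), 1.01)
})

test_that("harmonious states are stored below threshold and pruned by the window", {
  ltm <- ltm_state(nu = 1, t_wind = 10, dk = 0.5)
  ltm <- update_harmonious(ltm, 1.0, central_nis = 2, t_now = 1)
  expect_length(ltm$values, 0) # above threshold: unchanged
  ltm <- update_harmonious(ltm, 1.0, central_nis = 0.5, t_now = 2)
  expect_equal(ltm$values, 1.0)
  # entry aged beyond t_wind is removed on the next update
  ltm <- update_harmonious(ltm, 4.0, central_nis = 0.5, t_now = 13)
  expect_equal(ltm$values, 4.0)
  expect_error(update_harmonious(ltm, 1, 0.5, t_now = 1), "non-decreasing")
  expect_error(ltm_state(t_wind = 10, dk = 3), "integer multiple")
})

test_that("LTM density mass equals the harmonious fraction of the window", {
  grid <- gravity_grid(0.05, 5, 0.01)
  ltm <- ltm_state(nu = 1, t_wind = 10, dk = 0.5) # n_wind = 20
  expect_equal(ltm_density(ltm, grid), numeric(grid$n)) # empty -> all zero

  # fully harmonious window at 1 g -> point mass 1
  for (k in 1:20) ltm <- update_harmonious(ltm, 1, 0.1, t_now = k * 0.5)
  d <- ltm_density(ltm, grid)
  expect_equal(sum(d), 1)
  expect_equal(d[grid$values == 1], 1)

  # half the window harmonious -> mass 0.5 at the bin
  ltm2 <- ltm_state(nu = 1, t_wind = 10, dk = 0.5)
  for (k in 1:20) {
    ltm2 <- update_harmonious(ltm2, 1, ifelse(k %% 2 == 0, 0.1, 5), k * 0.5)
  }
  d2 <- ltm_density(ltm2, grid)
  expect_equal(sum(d2), 0.5)
  expect_equal(d2[grid$values == 1], 0.5)
})

test_that("the LTM priority weight is the shifted sigmoid of the jitter width", {
  expect_equal(mixture_weight(0, chi2 = 4), 0)
  expect_equal(mixture_weight(log(3) / 4, chi2 = 4), 0.25)
  expect_lt(mixture_weight(8, chi2 = 4), 0.5) # approaches 1/2 from below
  expect_gt(mixture_weight(8, chi2 = 4), 0.49)
  s <- seq(0, 2, by = 0.05)
  expect_true(all(diff(mixture_weight(s, chi2 = 4)) > 0)) # strictly increasing
})

test_that("the mixture transition density is proper and reduces to STM", {
  grid <- gravity_grid(0.05, 5, 0.01)
  tm <- transition_model(chi2 = 4, grid = grid)
  ltm_empty <- ltm_state(nu = 1, t_wind = 10, dk = 0.5)
  stm <- stm_state(hml = 1, c_jitter = 0.1)

  # empty LTM: equals STM density exactly (identical object)
  expect_identical(
    transition_density(1.2, stm, ltm_empty, tm),
    stm_density(1.2, stm$sigma, grid)
  )

  # populated LTM: proper density with extra mass at the learned state
  ltm <- ltm_empty
  for (k in 1:20) ltm <- update_harmonious(ltm, 4, 0.1, k * 0.5)
  set.seed(11)
  for (i in 1:10) {
    stm_i <- stm_state(hml = runif(1, 0.01, 5), c_jitter = runif(1, 0.01, 1))
    d <- transition_density(runif(1, 0.1, 4.9), stm_i, ltm, tm)
    expect_equal(sum(d), 1, tolerance = 1e-12)
  }
  # exploration + memory at 4 g: more mass at the 4 g bin than pure STM
  stm_explore <- stm_state(hml = 0, c_jitter = 10) # sigma = sigma_max
  d_mix <- transition_density(1, stm_explore, ltm, tm)
  d_stm <- stm_density(1, stm_explore$sigma, grid)
  expect_gt(d_mix[grid$values == 4], d_stm[grid$values == 4])
})

test_that("exploration-exploitation composition is monotone in the likelihood history", {
  # sigma nonincreasing in HML; W nondecreasing in sigma; so a rising HML
  # ramp must produce nonincreasing sigma and W.
  hml_ramp <- seq(0.01, 50, length.out = 40)
  sigmas <- vapply(hml_ramp, function(h) {
    jitter_sigma(stm_state(hml = h, c_jitter = 0.5))$sigma
  }, numeric(1))
  expect_true(all(diff(sigmas) <= 0))
  expect_true(all(diff(mixture_weight(sigmas, chi2 = 4)) <= 0))
})

test_that("learned states vanish after a full window away (LTM forgetting)", {
  grid <- gravity_grid(0.05, 5, 0.01)
  ltm <- ltm_state(nu = 1, t_wind = 10, dk = 0.5)
  for (k in 1:20) ltm <- update_harmonious(ltm, 1, 0.1, k * 0.5)
  expect_gt(sum(ltm_density(ltm, grid)), 0)
  # > t_wind of non-harmonious steps: memory must be empty
  for (k in 21:42) ltm <- update_harmonious(ltm, 4, 100, k * 0.5)
  expect_identical(ltm_density(ltm, grid), numeric(grid$n))
})

test_that("transition sampling is seed-deterministic, concentrated, and matches its density", {
  grid <- gravity_grid(0.76, 1.25, 0.01)
  tm <- transition_model(chi2 = 4, grid = grid)
  ltm <- ltm_state(nu = 1, t_wind = 10, dk = 0.5)
  stm <- stm_state(hml = 1e9, c_jitter = 1, sigma_min = 0.005)

  parents <- rep(c(1, 1.1), each = 10)
  set.seed(5)
  a <- sample_transitions(parents, stm, ltm, tm)
  set.seed(5)
  b <- sample_transitions(parents, stm, ltm, tm)
  expect_identical(a, b)
  expect_true(all(a %in% grid$values))
  # sigma at its minimum, no LTM: children stay within 3 sigma of parents
  expect_true(all(abs(a - parents) <= 3 * stm$sigma + 1e-12))

  # 1e5 draws from one fixed density vs expected frequencies
  stm2 <- stm_state(hml = 1, chi1 = 1, c_jitter = 0.1) # sigma = 0.1
  dens <- transition_density(1, stm2, ltm, tm)
  set.seed(9)
  draws <- sample_transitions(rep(1, 1e5), stm2, ltm, tm)
  counts <- tabulate(match(draws, grid$values), nbins = grid$n)
  gof <- suppressWarnings(stats::chisq.test(counts, p = dens))
  expect_gt(gof$p.value, 0.01)
})
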