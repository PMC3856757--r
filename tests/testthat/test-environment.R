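test_that("gradient optima and multipliers are the stated linear functions", {
  g <- build_gradient(50, 0.4, 0.04)
  expect_equal(g$optima[1], -9.8)
  expect_equal(g$optima[50], 9.8)
  expect_equal(unique(round(diff(g$optima), 12)), 0.4)
  expect_equal(sum(g$optima), 0)
  # multiplier line has slope expression_slope exactly and equals optimum/10
  expect_equal(unique(round(diff(g$multipliers), 12)), 0.04)
  expect_equal(g$multipliers, g$optima / 10)
  # single-deme gradient is flat with midpoint 1
  g1 <- build_gradient(1, 0.4, 0.04)
  expect_equal(g1$optima, 0)
  expect_equal(g1$midpoint, 1)
  expect_error(build_gradient(0), "positive")
  expect_error(build_gradient(10, Inf), "finite")
})

test_that("temporal_spec validates its fields", {
  expect_error(temporal_spec("p1", tau_pct = -1), "non-negative")
  expect_error(temporal_spec("p1", rho_among = 1), "inside")
  expect_error(temporal_spec("p3", corr_within = 1.5), "\\[-1, 1\\]")
  expect_error(temporal_spec("p1", corr_within = 0.5), "p3")
  expect_silent(temporal_spec("p3", corr_within = 0.5))
})

test_that("tau is a percentage of the gradient optimum span", {
  g <- build_gradient()
  expect_equal(tau_units(temporal_spec("p1", tau_pct = 10), g), 1.96)
  # single-deme runs use the default-gradient 19.6-unit base
  g1 <- build_gradient(1)
  expect_equal(tau_units(temporal_spec("p2", tau_pct = 10), g1), 1.96)
})

test_that("patterns pin the right stage to the gradient", {
  g <- build_gradient(10)
  set.seed(1)
  # tau = 0: both stages equal the optima every generation
  e0 <- env_init(g, temporal_spec("p3", tau_pct = 0))
  for (i in 1:3) e0 <- step_temporal(e0)
  expect_identical(e0$dev_env, g$optima)
  expect_identical(e0$sel_env, g$optima)
  # p1: development fixed; selection varies
  e1 <- env_init(g, temporal_spec("p1", tau_pct = 10))
  e1 <- step_temporal(e1)
  expect_identical(e1$dev_env, g$optima)
  expect_false(identical(e1$sel_env, g$optima))
  # p2: selection fixed; development varies
  e2 <- env_init(g, temporal_spec("p2", tau_pct = 10))
  e2 <- step_temporal(e2)
  expect_identical(e2$sel_env, g$optima)
  expect_false(identical(e2$dev_env, g$optima))
})

test_that("AR(1) deviations have stationary SD tau and lag-1 autocorr rho", {
  g <- build_gradient(2)
  n <- 20000L
  for (rho in c(0, 0.5, -0.75)) {
    set.seed(42 + round(100 * rho))
    e <- env_init(g, temporal_spec("p1", tau_pct = 10, rho_among = rho))
    tau <- e$tau
    dev <- numeric(n)
    for (t in seq_len(n)) {
      e <- step_temporal(e)
      dev[t] <- e$sel_state[1]
    }
    # sample SD within 3 SE of tau; SE inflated by autocorrelation
    se_sd <- tau / sqrt(2 * n) * sqrt((1 + rho^2) / (1 - rho^2))
    expect_lt(abs(sd(dev) - tau), 3 * se_sd)
    r1 <- cor(dev[-1], dev[-n])
    expect_lt(abs(r1 - rho), 3 * sqrt((1 - rho^2)^2 / n) + 3 / sqrt(n))
  }
})

test_that("within-generation innovation correlation matches corr_within", {
  g <- build_gradient(2)
  n <- 20000L
  for (cw in c(0.5, -0.75)) {
    set.seed(7 + round(10 * cw))
    e <- env_init(g, temporal_spec("p3", tau_pct = 10, corr_within = cw))
    devs <- matrix(0, n, 2)
    for (t in seq_len(n)) {
      e <- step_temporal(e)
      devs[t, ] <- c(e$dev_state[1], e$sel_state[1])
    }
    expect_lt(abs(cor(devs[, 1], devs[, 2]) - cw), 3 / sqrt(n))
  }
  # perfect carry-over: selection environment equals development environment
  set.seed(5)
  e <- env_init(g, temporal_spec("p3", tau_pct = 25, corr_within = 1))
  for (t in 1:50) {
    e <- step_temporal(e)
    expect_identical(e$sel_env, e$dev_env)
  }
})

test_that("synchronized variation is identical across demes", {
  g <- build_gradient(20)
  set.seed(9)
  e <- env_init(g, temporal_spec("p3", tau_pct = 10, rho_among = 0.5,
                                 synchronized = TRUE))
  for (t in 1:20) {
    e <- step_temporal(e)
    expect_equal(length(unique(e$dev_state)), 1L)
    expect_equal(length(unique(e$sel_state)), 1L)
  }
})

test_that("expression multiplier maps the development environment by the fixed ratio", {
  g <- build_gradient()
  e <- env_init(g)
  expect_equal(expression_multiplier(e, 50), 0.98)
  expect_equal(expression_multiplier(e, 26) + expression_multiplier(e, 25), 0)
  # perturbed development environment at deme 25 (optimum -0.2): +1.0 on the
  # trait scale maps to +0.1 on the multiplier scale
  e$dev_env[25] <- e$dev_env[25] + 1.0
  expect_equal(expression_multiplier(e, 25), 0.08)
  expect_error(expression_multiplier(e, 51), "out of range")
  expect_error(expression_multiplier(e, 0), "out of range")
})
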