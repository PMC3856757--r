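test_that("mean plasticity averages residents within demes, demes unweighted", {
  g <- build_gradient(3)
  # deme 1: everyone sum P = 10; deme 2: everyone 0; deme 3 empty
  alleles <- rbind(cbind(matrix(0, 40, 10), matrix(1, 40, 10)),
                   matrix(0, 10, 20))
  pop <- plastisim:::new_population(alleles, c(rep(1L, 40), rep(2L, 10)))
  m <- mean_plasticity(pop, 3)
  expect_equal(m$deme_means, c(10, 0, NA))
  expect_equal(m$overall, 5) # unweighted despite unequal deme sizes
  empty <- plastisim:::subset_population(pop, integer(0))
  expect_error(mean_plasticity(empty, 3), "empty")
})

test_that("relative plasticity standardizes to the optimal reaction norm", {
  g <- build_gradient()
  expect_equal(optimal_plastic_sum(g), 10)
  expect_equal(relative_plasticity(10, g), 1)
  expect_equal(relative_plasticity(0, g), 0)
  expect_equal(relative_plasticity(-5, g), -0.5)
  # affine-invariant to the slopes as long as their ratio is fixed
  g2 <- build_gradient(50, 0.8, 0.08)
  expect_equal(relative_plasticity(7, g2), relative_plasticity(7, g))
  g0 <- build_gradient(50, 0.4, 0)
  expect_error(relative_plasticity(1, g0), "undefined")
})

test_that("replicate aggregation averages successes and reports the sample CV", {
  cfg <- run_config(n_demes = 5, n_generations = 10)
  # 20 identical replicates: CV 0
  s0 <- aggregate_replicates(fake_replicate_set(rep(0.8, 20), cfg))
  expect_equal(s0$cv_pct, 0)
  expect_equal(s0$relative_plasticity, 0.8)
  # {0.9, 1.1}: mean 1, sample-SD CV 10 * sqrt(2) / 10 ... = 14.14? no:
  # sd(c(.9, 1.1)) = 0.1414; CV = 14.14%
  s1 <- aggregate_replicates(fake_replicate_set(c(0.9, 1.1), cfg))
  expect_equal(s1$relative_plasticity, 1)
  expect_equal(s1$cv_pct, 100 * sd(c(0.9, 1.1)) / 1)
  # extinct runs are excluded from averages but counted in the
  # extinction probability
  s2 <- aggregate_replicates(fake_replicate_set(c(0.5, 0.5), cfg,
                                                n_extinct = 2L))
  expect_equal(s2$relative_plasticity, 0.5)
  expect_equal(s2$n_success, 2L)
  expect_equal(s2$extinction_probability_pct, 50)
  # zero successes: summary is missing
  s3 <- aggregate_replicates(fake_replicate_set(numeric(0), cfg,
                                                n_extinct = 3L))
  expect_true(is.na(s3$relative_plasticity))
  expect_equal(s3$extinction_probability_pct, 100)
})

test_that("end-state value averages the final window", {
  cfg <- run_config(n_demes = 5, n_generations = 10)
  r <- fake_result(0.6, cfg, G = 300L)
  r$trajectory[201:300] <- 8 # last 100 generations
  expect_equal(end_state_relative_plasticity(r, window = 100), 0.8)
  expect_error(end_state_relative_plasticity(fake_result(0, cfg,
                                                         extinct = TRUE)),
               "extinct")
})

test_that("equilibrium_check flags trends and short trajectories", {
  flat <- equilibrium_check(rep(3, 2000), window = 500)
  expect_equal(flat$verdict, "no-trend")
  expect_equal(flat$end_state, 3)
  rising <- equilibrium_check(seq(0, 10, length.out = 2000), window = 500)
  expect_equal(rising$verdict, "trend")
  expect_equal(equilibrium_check(rep(1, 100), window = 500)$verdict,
               "insufficient")
})
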