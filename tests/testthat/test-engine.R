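test_that("soft selection refills every occupied deme to capacity", {
  g <- build_gradient(10)
  env <- env_init(g)
  cfg <- run_config(n_demes = 10, n_generations = 5)
  set.seed(1)
  pop <- perfect_population(g, 100)
  out <- run_generation(pop, env, cfg)
  expect_false(out$extinct)
  expect_equal(tabulate(out$pop$deme, 10), rep(100L, 10))

  # a single survivor refills its deme (self-pairing)
  lone <- plastisim:::subset_population(perfect_population(g, 1), 3L)
  kids <- reproduce_deme(lone, capacity = 100)
  expect_equal(pop_size(kids), 100L)
  expect_true(all(kids$deme == 3L))
  # no occupants, no newborns
  none <- plastisim:::subset_population(lone, integer(0))
  expect_equal(pop_size(reproduce_deme(none, 100)), 0L)
})

test_that("population size after reproduction is capacity x occupied demes", {
  set.seed(2)
  for (i in 1:5) {
    D <- sample(2:20, 1)
    g <- build_gradient(D)
    pop <- init_population(g, sample(1:30, 1))
    # randomly thin so some demes may empty out
    keep <- runif(pop_size(pop)) < 0.3
    pop <- plastisim:::subset_population(pop, keep)
    if (pop_size(pop) == 0L) next
    out <- plastisim:::reproduce_population(pop, 50L, D, 0.1, 0.1)
    n_occ <- length(unique(pop$deme))
    expect_equal(pop_size(out), 50L * n_occ)
    expect_setequal(unique(out$deme), unique(pop$deme))
  }
})

test_that("offspring alleles come from parents in the same deme", {
  # give each deme a unique allele signature; with no mutation every newborn
  # must carry its own deme's signature
  D <- 5L
  g <- build_gradient(D)
  n <- 50L * D
  deme <- rep(1:D, each = 50L)
  alleles <- matrix(rep(deme, 20), n, 20)
  pop <- plastisim:::new_population(alleles, deme)
  set.seed(3)
  out <- plastisim:::reproduce_population(pop, 20L, D, 0, 0)
  expect_true(all(out$alleles == out$deme))
})

test_that("life-history order controls whether selection precedes dispersal", {
  # phenotypes match the natal optimum exactly and selection is very strong.
  # select_first: everyone is selected at home, survives, then scatters --
  # the next generation fills all demes to capacity. move_first: island
  # dispersal at rate ~1 sends almost everyone to a deme whose optimum is
  # >= 2 units away (sigma 0.1 => fitness ~ 0), crashing the census.
  cfg_base <- list(n_demes = 10, optimum_slope = 2, expression_slope = 0.2,
                   sigma = 0.1, migration = "island", dispersal_rate = 0.99,
                   n_generations = 1)
  g <- build_gradient(10, 2, 0.2)
  env <- env_init(g)
  set.seed(4)
  pop <- perfect_population(g, 100)
  sel_first <- run_generation(pop, env,
                              run_config(c(cfg_base, order = "select_first")))
  expect_equal(pop_size(sel_first$pop), 1000L)
  set.seed(4)
  pop <- perfect_population(g, 100)
  move_first <- run_generation(pop, env,
                               run_config(c(cfg_base, order = "move_first")))
  # survivors are essentially only the ~1% who stayed home, so some demes
  # empty out and the census falls below the full 10 x 100
  expect_lt(pop_size(move_first$pop), 1000L)
})

test_that("runs are reproducible from the seed and replicate seeds are stable", {
  cfg <- run_config(n_demes = 8, n_generations = 30, dispersal_rate = 0.2,
                    pattern = "p1", tau_pct = 10)
  r1 <- run_simulation(cfg, seed = 99)
  r2 <- run_simulation(cfg, seed = 99)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$end_state, r2$end_state)
  # counter-based child seeds: below 2^31 and order-independent
  s <- vapply(1:60, function(k) plastisim:::child_seed(123, k), 0)
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(anyDuplicated(s) > 0)
  expect_identical(plastisim:::child_seed(123, 17),
                   vapply(17:1, function(k) plastisim:::child_seed(123, k),
                          0)[1])
})

test_that("benign parameters succeed on every attempt", {
  cfg <- run_config(n_demes = 10, n_generations = 60, dispersal_rate = 0.3)
  reps <- run_replicates(cfg, n_success = 5, max_attempts = 60,
                         master_seed = 11)
  expect_equal(reps$n_attempts, 5L)
  expect_equal(reps$n_success, 5L)
  expect_equal(reps$extinction_probability, 0)
})

test_that("total wipe-out sets the extinct flag and truncates the run", {
  # sigma tiny, phenotypes far from every optimum: all die in generation 1
  cfg <- run_config(n_demes = 4, deme_capacity = 25, n_generations = 50,
                    sigma = 0.01)
  set.seed(6)
  r <- run_simulation(cfg, seed = 8)
  expect_true(r$extinct)
  expect_equal(r$generations_completed, 0L)
  expect_true(all(is.na(r$trajectory)))
  expect_null(r$end_state)
  reps <- run_replicates(cfg, n_success = 2, max_attempts = 7,
                         master_seed = 5)
  expect_equal(reps$n_attempts, 7L)
  expect_equal(reps$n_success, 0L)
  expect_equal(reps$extinction_probability, 1)
})
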