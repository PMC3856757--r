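# Shared fixtures, built in code.

# Population in which every individual expresses the optimal reaction norm:
# nonplastic alleles all 0 (sum N = 0) and plastic alleles all 1
# (sum P = 10), so the phenotype equals the local optimum in every deme when
# there is no temporal perturbation.
perfect_population <- function(gradient, deme_size = 100L) {
  n <- gradient$n_demes * deme_size
  alleles <- cbind(matrix(0, n, 10), matrix(1, n, 10))
  plastisim:::new_population(alleles,
                             rep(seq_len(gradient$n_demes), each = deme_size))
}

# Minimal hand-built sim_result for aggregation arithmetic tests.
fake_result <- function(rel_plasticity, config, extinct = FALSE, G = 200L) {
  pstar <- optimal_plastic_sum(config$gradient)
  D <- config$n_demes
  traj <- rep(rel_plasticity * pstar, G)
  structure(
    list(trajectory = if (extinct) rep(NA_real_, G) else traj,
         deme_trajectory = matrix(if (extinct) NA_real_ else
           rel_plasticity * pstar, G, D),
         occupied = rep(D, G), end_state = NULL, extinct = extinct,
         generations_completed = if (extinct) 7L else G,
         seed = 0L, config = config),
    class = "sim_result"
  )
}

fake_replicate_set <- function(rel_values, config, n_extinct = 0L) {
  results <- c(lapply(rel_values, fake_result, config = config),
               if (n_extinct > 0L)
                 lapply(seq_len(n_extinct), function(i)
                   fake_result(0, config, extinct = TRUE)))
  structure(
    list(results = results, n_attempts = length(results),
         n_success = length(rel_values),
         extinction_probability = n_extinct / length(results),
         master_seed = 0L, config = config),
    class = "replicate_set"
  )
}
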