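# Generational engine: life-cycle orchestration, soft-selection
# reproduction, extinction detection and the replicate protocol.

# Vectorized reproduction across all occupied demes. Survivors in each
# occupied deme are paired uniformly at random with replacement (self-pairing
# allowed, so a single survivor can refill its deme), each pair leaving one
# offspring, until the deme holds `capacity` newborns — soft selection: the
# local census after reproduction is independent of how many survived.
reproduce_population <- function(pop, capacity, n_demes,
                                 mutation_rate, mutation_sd) {
  n <- pop_size(pop)
  if (n == 0L)
    return(new_population(pop$alleles[0, , drop = FALSE], integer(0)))
  out <- .repro_cpp(pop$alleles, pop$deme, as.integer(n_demes),
                    as.integer(capacity), mutation_rate, mutation_sd)
  new_population(out$alleles, out$deme)
}

#' Refill one deme by random mating
#'
#' Reproduction within a single deme under soft selection: pairs of survivors
#' are assembled uniformly at random with replacement (a pair may be the same
#' individual twice), each pair produces one offspring via the rules of
#' [make_offspring()], until `capacity` newborns exist. A deme with no
#' occupants produces no newborns; a deme with at least one occupant always
#' returns exactly `capacity`.
#'
#' Uses the R global random number stream.
#'
#' @param occupants A `population` whose individuals all share one deme (the
#'   survivors present after selection and dispersal).
#' @param capacity Deme carrying capacity (default 100).
#' @param mutation_rate,mutation_sd Per-allele mutation parameters.
#' @return A `population` of newborns in the same deme.
#' @export
reproduce_deme <- function(occupants, capacity = 100L,
                           mutation_rate = 0.1, mutation_sd = 0.1) {
  n <- pop_size(occupants)
  if (n == 0L)
    return(new_population(occupants$alleles[0, , drop = FALSE], integer(0)))
  d <- unique(occupants$deme)
  if (length(d) != 1L)
    stop("`occupants` must all be in one deme", call. = FALSE)
  out <- reproduce_population(occupants, capacity, n_demes = max(d),
                              mutation_rate, mutation_sd)
  out
}

#' Advance the population by one full generation
#'
#' Executes one life cycle: the temporal environment update, development
#' (phenotypes fixed from the development environment of the natal deme),
#' then either dispersal followed by selection (`"move_first"`) or selection
#' followed by dispersal (`"select_first"`), and finally reproduction under
#' soft selection. If no individual survives to reproduction anywhere the
#' metapopulation is extinct and the returned population is empty.
#'
#' Uses the R global random number stream.
#'
#' @param pop A `population` of newborns.
#' @param env A `deme_environment`.
#' @param config A [run_config()].
#' @return A list with `pop` (next generation's newborns), `env` (updated
#'   environment) and `extinct` (logical).
#' @export
run_generation <- function(pop, env, config) {
  env <- step_temporal(env)
  pop <- develop_population(pop, env)
  if (config$order == "move_first") {
    pop <- disperse(pop, config$dispersal, config$n_demes)
    pop <- apply_selection(pop, env, config$sigma)
  } else {
    pop <- apply_selection(pop, env, config$sigma)
    pop <- disperse(pop, config$dispersal, config$n_demes)
  }
  if (pop_size(pop) == 0L)
    return(list(pop = pop, env = env, extinct = TRUE))
  pop <- reproduce_population(pop, config$deme_capacity, config$n_demes,
                              config$mutation_rate, config$mutation_sd)
  list(pop = pop, env = env, extinct = FALSE)
}

#' Run one replicate simulation
#'
#' Initializes the founding population, then iterates [run_generation()] for
#' `config$n_generations` generations, recording the mean plasticity (the
#' deme-mean of each newborn's plastic allelic sum, averaged unweighted over
#' occupied demes) at every generation. A run that loses every individual
#' before reproduction in some generation stops there with `extinct = TRUE`.
#'
#' @param config A [run_config()].
#' @param seed Integer seed for this replicate; `NULL` continues the current
#'   R random number stream.
#' @return An object of class `sim_result`: `trajectory` (per-generation
#'   overall mean plasticity; `NA` beyond extinction), `deme_trajectory`
#'   (generations x demes matrix of deme means, `NA` where a deme was
#'   empty), `occupied` (occupied-deme count per generation), `end_state`
#'   (per-deme data frame: optimum, mean plastic sum, mean nonplastic sum,
#'   mean phenotype of the final cohort), `extinct`,
#'   `generations_completed` and `seed`.
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) set.seed(seed)
  G <- config$n_generations
  D <- config$n_demes
  env <- env_init(config$gradient, config$temporal)
  pop <- init_population(config$gradient, config$deme_capacity)

  traj <- rep(NA_real_, G)
  deme_traj <- matrix(NA_real_, nrow = G, ncol = D)
  occupied <- rep(NA_integer_, G)
  extinct <- FALSE
  completed <- 0L
  for (g in seq_len(G)) {
    stepped <- run_generation(pop, env, config)
    env <- stepped$env
    if (stepped$extinct) {
      extinct <- TRUE
      break
    }
    pop <- stepped$pop
    ps <- rowSums(pop$alleles[, PLASTIC_COLS, drop = FALSE])
    dm <- rowsum(ps, pop$deme, reorder = TRUE) / config$deme_capacity
    occ <- as.integer(rownames(dm))
    deme_traj[g, occ] <- dm
    traj[g] <- mean(dm)
    occupied[g] <- length(occ)
    completed <- g
  }

  end_state <- NULL
  if (!extinct) {
    pop <- develop_population(pop, env) # phenotypes of the final cohort
    s <- allelic_sums(pop)
    deme_mean <- function(x) {
      m <- rowsum(x, pop$deme) / config$deme_capacity
      out <- rep(NA_real_, D)
      out[as.integer(rownames(m))] <- m
      out
    }
    end_state <- data.frame(
      deme = seq_len(D),
      optimum = config$gradient$optima,
      mean_plastic = deme_mean(s$plastic),
      mean_nonplastic = deme_mean(s$nonplastic),
      mean_phenotype = deme_mean(pop$phenotype)
    )
  }
  structure(
    list(trajectory = traj, deme_trajectory = deme_traj,
         occupied = occupied, end_state = end_state, extinct = extinct,
         generations_completed = completed, seed = seed, config = config),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  if (x$extinct) {
    cat("Simulation: EXTINCT at generation", x$generations_completed + 1L,
        "\n")
  } else {
    rp <- end_state_relative_plasticity(x)
    cat("Simulation:", x$generations_completed, "generations;",
        sprintf("end-state relative plasticity %.3f\n", rp))
  }
  invisible(x)
}

# Deterministic child seed for replicate k of a master seed; counter-based so
# replicate k is reproducible independent of execution order. Kept below
# 2^31 - 1.
child_seed <- function(master_seed, k) {
  (as.double(master_seed) + 99991 * as.double(k)) %% 2147483629
}

#' Run replicates until enough succeed
#'
#' Repeats [run_simulation()] with deterministic per-replicate seeds until
#' `n_success` runs finish without metapopulation extinction, or
#' `max_attempts` runs have been attempted. Reported outcomes downstream
#' (see [aggregate_replicates()]) average over successful replicates only;
#' the extinction probability is the extinct fraction of attempted runs.
#'
#' @param config A [run_config()].
#' @param n_success Target number of non-extinct replicates (default 20).
#' @param max_attempts Cap on total attempts (default 60).
#' @param master_seed Master seed from which per-replicate seeds are derived.
#' @return An object of class `replicate_set`: `results` (all attempted
#'   `sim_result`s), `n_attempts`, `n_success`, `extinction_probability`
#'   (fraction in [0, 1]), `master_seed` and `config`.
#' @export
run_replicates <- function(config, n_success = 20L, max_attempts = 60L,
                           master_seed = 1L) {
  stopifnot(inherits(config, "run_config"), n_success >= 1, max_attempts >= 1)
  results <- vector("list", max_attempts)
  successes <- 0L
  k <- 0L
  while (successes < n_success && k < max_attempts) {
    k <- k + 1L
    res <- run_simulation(config, seed = child_seed(master_seed, k))
    results[[k]] <- res
    if (!res$extinct) successes <- successes + 1L
  }
  results <- results[seq_len(k)]
  structure(
    list(results = results, n_attempts = k, n_success = successes,
         extinction_probability = mean(vapply(results, `[[`, TRUE, "extinct")),
         master_seed = master_seed, config = config),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("Replicate set:", x$n_success, "successes in", x$n_attempts,
      sprintf("attempts (extinction probability %.0f%%)\n",
              100 * x$extinction_probability))
  invisible(x)
}
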