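# Genetic architecture: 5 diploid nonplastic loci + 5 diploid plastic loci.
# A population's alleles live in an n x 20 matrix; columns 1:10 hold the
# nonplastic allelic values (locus l in columns 2l-1, 2l) and columns 11:20
# the plastic ones. Allelic values are continuous after generation 0.
N_LOCI <- 5L
N_ALLELE_COLS <- 4L * N_LOCI
NONPLASTIC_COLS <- 1:10
PLASTIC_COLS <- 11:20
INIT_ALLELE_VALUES <- c(-2, -1, 0, 1, 2)

#' Construct a genotype
#'
#' A genotype holds the 10 nonplastic and 10 plastic allelic values of one
#' diploid individual (5 loci of each class, 2 alleles per locus). The sum of
#' the nonplastic values is the reaction-norm intercept at the gradient
#' midpoint; the sum of the plastic values, scaled by the local expression
#' multiplier, is its slope contribution.
#'
#' @param nonplastic Numeric vector of 10 nonplastic allelic values
#'   (locus l occupies positions 2l-1 and 2l).
#' @param plastic Numeric vector of 10 plastic allelic values.
#' @return An object of class `genotype`.
#' @export
genotype <- function(nonplastic = numeric(10), plastic = numeric(10)) {
  if (length(nonplastic) != 10L || length(plastic) != 10L)
    stop("a genotype has exactly 10 allelic values per class", call. = FALSE)
  if (!all(is.finite(nonplastic)) || !all(is.finite(plastic)))
    stop("allelic values must be finite", call. = FALSE)
  structure(list(nonplastic = as.numeric(nonplastic),
                 plastic = as.numeric(plastic)),
            class = "genotype")
}

#' Phenotype determination at development
#'
#' The phenotype is the sum of the nonplastic allelic values plus the
#' expression multiplier times the sum of the plastic allelic values. It is
#' deterministic (no random component of phenotypic variation) and fixed at
#' the moment of development: later dispersal or environmental change never
#' recomputes it.
#'
#' @param genotype A [genotype()].
#' @param multiplier Expression multiplier of the development environment
#'   (see [expression_multiplier()]).
#' @return The phenotype, trait units.
#' @examples
#' g <- genotype(plastic = rep(1, 10))   # sum P = 10, sum N = 0
#' develop(g, 0.98)                      # 9.8, the terminal-deme optimum
#' @export
develop <- function(genotype, multiplier) {
  stopifnot(inherits(genotype, "genotype"), is.finite(multiplier))
  sum(genotype$nonplastic) + multiplier * sum(genotype$plastic)
}

#' Mate two individuals
#'
#' Produces one offspring genotype. At every locus the offspring receives one
#' allelic value drawn at random from each parent's two, with free
#' recombination (independent assortment across all 10 loci). Each of the 20
#' resulting allelic values then mutates independently with probability
#' `mutation_rate` by adding a Normal(0, `mutation_sd`) deviate — an
#' infinite-alleles model on a continuous scale.
#'
#' Uses the R global random number stream.
#'
#' @param parent_a,parent_b [genotype()] objects.
#' @param mutation_rate Per-allele mutation probability (default 0.1).
#' @param mutation_sd Standard deviation of the mutational step (default 0.1
#'   trait units).
#' @return The offspring `genotype`.
#' @export
make_offspring <- function(parent_a, parent_b,
                           mutation_rate = 0.1, mutation_sd = 0.1) {
  stopifnot(inherits(parent_a, "genotype"), inherits(parent_b, "genotype"),
            mutation_rate >= 0, mutation_rate <= 1, mutation_sd >= 0)
  # one gamete allele per locus: position 2l-1 or 2l of the parent's pair
  gamete <- function(vals10) {
    vals10[2L * seq_len(N_LOCI) - 1L + (runif(N_LOCI) < 0.5)]
  }
  pair_up <- function(from_a, from_b) {
    out <- numeric(2L * N_LOCI)
    out[c(TRUE, FALSE)] <- from_a
    out[c(FALSE, TRUE)] <- from_b
    out
  }
  child <- c(pair_up(gamete(parent_a$nonplastic), gamete(parent_b$nonplastic)),
             pair_up(gamete(parent_a$plastic), gamete(parent_b$plastic)))
  mut <- runif(N_ALLELE_COLS) < mutation_rate
  if (any(mut) && mutation_sd > 0)
    child[mut] <- child[mut] + rnorm(sum(mut), 0, mutation_sd)
  genotype(nonplastic = child[1:10], plastic = child[11:20])
}

#' Initialize a founding population
#'
#' Fills every deme with `deme_size` newborn individuals whose 20 allelic
#' values are drawn independently and uniformly from {-2, -1, 0, 1, 2}.
#' Phenotypes are not yet determined (development happens inside the
#' generation cycle).
#'
#' Uses the R global random number stream.
#'
#' @param gradient A [build_gradient()] object.
#' @param deme_size Individuals born per deme (100 on the gradient; 1000 for
#'   single-deme, temporal-only runs).
#' @return An object of class `population`: a list with `alleles` (n x 20
#'   matrix, nonplastic columns 1:10, plastic columns 11:20), `deme` and
#'   `natal` (current and birth deme indices) and `phenotype` (NA until
#'   development).
#' @export
init_population <- function(gradient, deme_size = 100L) {
  stopifnot(inherits(gradient, "gradient_spec"), deme_size >= 1)
  deme_size <- as.integer(deme_size)
  n <- gradient$n_demes * deme_size
  alleles <- matrix(
    sample(INIT_ALLELE_VALUES, n * N_ALLELE_COLS, replace = TRUE),
    nrow = n, ncol = N_ALLELE_COLS
  )
  deme <- rep(seq_len(gradient$n_demes), each = deme_size)
  new_population(alleles, deme)
}

# Internal constructor from raw state.
new_population <- function(alleles, deme, natal = deme,
                           phenotype = rep(NA_real_, nrow(alleles))) {
  structure(list(alleles = alleles, deme = as.integer(deme),
                 natal = as.integer(natal), phenotype = phenotype),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Population:", nrow(x$alleles), "individuals in",
      length(unique(x$deme)), "occupied deme(s)\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population`.
#' @return Integer count.
#' @export
pop_size <- function(pop) nrow(pop$alleles)

#' Per-individual allelic sums
#'
#' Row sums of the nonplastic and plastic allelic values: the reaction-norm
#' intercept and (unscaled) slope of every individual.
#'
#' @param pop A `population`.
#' @return A list with numeric vectors `nonplastic` and `plastic`.
#' @export
allelic_sums <- function(pop) {
  list(nonplastic = rowSums(pop$alleles[, NONPLASTIC_COLS, drop = FALSE]),
       plastic = rowSums(pop$alleles[, PLASTIC_COLS, drop = FALSE]))
}

# Vectorized development: fixes phenotypes for all individuals using the
# development environment of their current (= natal) deme.
develop_population <- function(pop, env) {
  s <- allelic_sums(pop)
  mult <- env$dev_env * (env$gradient$expression_slope /
                           env$gradient$optimum_slope)
  pop$phenotype <- s$nonplastic + mult[pop$deme] * s$plastic
  pop
}

# Subset a population by a logical or integer index, keeping all fields
# aligned.
subset_population <- function(pop, keep) {
  new_population(pop$alleles[keep, , drop = FALSE], pop$deme[keep],
                 pop$natal[keep], pop$phenotype[keep])
}
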