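#' Gaussian survival probability
#'
#' Viability under stabilizing selection: the probability of surviving is a
#' Gaussian function of the difference between an individual's phenotype and
#' the locally optimal phenotype,
#'   W = exp(-(T - theta)^2 / (2 sigma^2)).
#' W lies in (0, 1], equals 1 at the optimum, is symmetric in the deviation,
#' and selection weakens as sigma grows.
#'
#' @param phenotype Phenotype(s) T, trait units.
#' @param optimum Local optimum theta, trait units (recycled).
#' @param sigma Strength-of-selection scale, trait units (> 0, default 2;
#'   larger sigma means weaker selection).
#' @return Survival probabilities, same length as the inputs.
#' @examples
#' gaussian_fitness(2, 0, sigma = 2)  # exp(-0.5)
#' @export
gaussian_fitness <- function(phenotype, optimum, sigma = 2) {
  if (!all(sigma > 0)) stop("`sigma` must be positive", call. = FALSE)
  exp(-((phenotype - optimum)^2) / (2 * sigma^2))
}

#' Apply viability selection
#'
#' Each individual survives independently with probability given by
#' [gaussian_fitness()] against the selection-stage environment of its
#' current deme: a uniform [0, 1] number is drawn and the individual dies if
#' its fitness is below it. Dead individuals are removed; phenotypes were
#' fixed at development and are not recomputed.
#'
#' Uses the R global random number stream.
#'
#' @param pop A `population` with phenotypes determined.
#' @param env A `deme_environment` (its `sel_env` supplies the optima).
#' @param sigma Strength of selection (default 2).
#' @return The surviving `population` (possibly empty).
#' @export
apply_selection <- function(pop, env, sigma = 2) {
  n <- pop_size(pop)
  if (n == 0L) return(pop)
  if (anyNA(pop$phenotype))
    stop("phenotypes must be determined before selection", call. = FALSE)
  w <- gaussian_fitness(pop$phenotype, env$sel_env[pop$deme], sigma)
  subset_population(pop, w >= runif(n))
}
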