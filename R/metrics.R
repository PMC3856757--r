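# Plasticity summary statistics and replicate aggregation.

#' Mean plasticity of a population
#'
#' The plasticity of a linear reaction norm is its slope, which in this model
#' is proportional to the sum of an individual's plastic allelic values. The
#' deme mean is the average plastic sum over residents; the overall mean is
#' the unweighted average of the deme means over occupied demes (empty demes
#' are excluded, not imputed).
#'
#' @param pop A `population`.
#' @param n_demes Number of demes D.
#' @return A list with `deme_means` (length D, `NA` for empty demes) and
#'   `overall` (mean over occupied demes).
#' @export
mean_plasticity <- function(pop, n_demes) {
  if (pop_size(pop) == 0L)
    stop("mean plasticity is undefined for an empty population",
         call. = FALSE)
  ps <- rowSums(pop$alleles[, PLASTIC_COLS, drop = FALSE])
  m <- rowsum(ps, pop$deme) / tabulate(pop$deme, n_demes)[sort(unique(pop$deme))]
  deme_means <- rep(NA_real_, n_demes)
  deme_means[as.integer(rownames(m))] <- m
  list(deme_means = deme_means, overall = mean(deme_means, na.rm = TRUE))
}

#' Standardize plasticity to the optimal reaction norm
#'
#' Divides a mean plastic allelic sum by the optimum-matching sum
#' `optimum_slope / expression_slope` (10 under the defaults), so 1 is a pure
#' plasticity outcome (the reaction norm tracks the local optima exactly), 0
#' is pure genetic differentiation (flat reaction norms), values above 1 are
#' hyperplastic (slope steeper than optimal) and negative values point
#' opposite to the gradient (countergradient-type norms).
#'
#' @param mean_plastic_sum Mean plastic allelic sum (scalar or vector).
#' @param gradient A [build_gradient()] object.
#' @return Relative plasticity, dimensionless.
#' @export
relative_plasticity <- function(mean_plastic_sum, gradient) {
  mean_plastic_sum / optimal_plastic_sum(gradient)
}

#' End-state relative plasticity of one run
#'
#' The reported end state is the mean of the overall plasticity trajectory
#' over the final `window` completed generations (a single-generation value
#' is noisy), standardized to the optimal reaction norm.
#'
#' @param result A [run_simulation()] result (non-extinct).
#' @param window Number of final generations to average (default 100,
#'   truncated to the trajectory length).
#' @return Relative plasticity at the end state.
#' @export
end_state_relative_plasticity <- function(result, window = 100L) {
  if (result$extinct)
    stop("end state is undefined for an extinct run", call. = FALSE)
  G <- result$generations_completed
  w <- min(window, G)
  tail_mean <- mean(result$trajectory[(G - w + 1L):G])
  relative_plasticity(tail_mean, result$config$gradient)
}

#' Aggregate a replicate set
#'
#' Averages end-state outcomes over the successful (non-extinct) replicates
#' only, as extinct runs have no end state. Also reports the coefficient of
#' variation of end-state relative plasticity across replicates (sample,
#' n - 1, standard deviation) and the extinction probability over all
#' attempts. With zero successes the summary values are `NA`.
#'
#' @param reps A [run_replicates()] result.
#' @param window Final-generation averaging window (see
#'   [end_state_relative_plasticity()]).
#' @return An object of class `plasticity_summary`: `deme_mean_plasticity`
#'   (per-deme mean plastic sum across successful runs),
#'   `mean_plasticity` (its across-deme mean), `relative_plasticity`,
#'   `cv_pct` (percent CV across replicates), `n_success`, `n_attempts`,
#'   `extinction_probability_pct`.
#' @export
aggregate_replicates <- function(reps, window = 100L) {
  stopifnot(inherits(reps, "replicate_set"))
  ok <- Filter(function(r) !r$extinct, reps$results)
  gradient <- reps$config$gradient
  if (length(ok) == 0L) {
    out <- list(deme_mean_plasticity = NULL, mean_plasticity = NA_real_,
                relative_plasticity = NA_real_, cv_pct = NA_real_,
                n_success = 0L, n_attempts = reps$n_attempts,
                extinction_probability_pct = 100 * reps$extinction_probability)
    return(structure(out, class = "plasticity_summary"))
  }
  per_run_rel <- vapply(ok, end_state_relative_plasticity, 0, window = window)
  # per-deme plastic sums averaged over the final window, then over runs
  deme_tail <- function(r) {
    G <- r$generations_completed
    w <- min(window, G)
    # a deme contributes only the generations in which it was occupied
    colMeans(r$deme_trajectory[(G - w + 1L):G, , drop = FALSE], na.rm = TRUE)
  }
  mat <- matrix(vapply(ok, deme_tail, numeric(gradient$n_demes)),
                nrow = gradient$n_demes)
  deme_means <- rowMeans(mat, na.rm = TRUE)
  overall <- mean(deme_means[is.finite(deme_means)])
  cv <- if (length(per_run_rel) > 1L)
    100 * stats::sd(per_run_rel) / abs(mean(per_run_rel))
  else NA_real_
  structure(
    list(deme_mean_plasticity = deme_means, mean_plasticity = overall,
         relative_plasticity = relative_plasticity(overall, gradient),
         per_replicate_relative = per_run_rel, cv_pct = cv,
         n_success = length(ok), n_attempts = reps$n_attempts,
         extinction_probability_pct = 100 * reps$extinction_probability),
    class = "plasticity_summary"
  )
}

#' @export
print.plasticity_summary <- function(x, ...) {
  cat("Plasticity summary over", x$n_success, "successful /", x$n_attempts,
      "attempted replicates\n")
  cat(sprintf("  relative plasticity    : %.3f\n", x$relative_plasticity))
  cat(sprintf("  CV across replicates   : %.1f%%\n", x$cv_pct))
  cat(sprintf("  extinction probability : %.0f%%\n",
              x$extinction_probability_pct))
  invisible(x)
}

#' Directional-trend check on a trajectory
#'
#' Decides whether a run has reached its equilibrium: a linear regression is
#' fitted to the final `window` generations and the verdict is `"no-trend"`
#' when the fitted total drift across the window, `|slope| * window`, does
#' not exceed `tol` (in the trajectory's own units), `"trend"` otherwise.
#' Trajectories shorter than `2 * window` return `"insufficient"`.
#'
#' @param trajectory Per-generation means (numeric vector).
#' @param window Number of final generations to test (default 500).
#' @param tol Maximum tolerated fitted drift across the window (default 0.5
#'   trajectory units).
#' @return A list with `verdict` (`"no-trend"`, `"trend"` or
#'   `"insufficient"`), `slope` (per generation) and `end_state` (mean over
#'   the window).
#' @export
equilibrium_check <- function(trajectory, window = 500L, tol = 0.5) {
  trajectory <- trajectory[!is.na(trajectory)]
  n <- length(trajectory)
  if (n < 2L * window)
    return(list(verdict = "insufficient", slope = NA_real_,
                end_state = NA_real_))
  y <- trajectory[(n - window + 1L):n]
  x <- seq_along(y)
  slope <- stats::cov(x, y) / stats::var(x)
  verdict <- if (abs(slope) * window <= tol) "no-trend" else "trend"
  list(verdict = verdict, slope = slope, end_state = mean(y))
}
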