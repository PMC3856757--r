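#' Linear environmental gradient
#'
#' Builds the static spatial gradient: a linear array of demes in which both
#' the locally optimal phenotype and the expression multiplier of the plastic
#' loci change linearly with deme position. With the defaults (50 demes,
#' optimum slope 0.4 trait units per deme) the optima run from -9.8 to +9.8
#' and adjacent demes differ by exactly 0.4 units. The expression multiplier
#' has slope 0.04 per deme, so the unperturbed multiplier in deme i is
#' 0.04 * (i - midpoint) and equals one tenth of the local optimum.
#'
#' Both lines are centred on the gradient midpoint (D + 1) / 2, so the optima
#' are symmetric about zero and sum to zero over demes. A single-deme
#' gradient is flat: optimum and multiplier are both 0.
#'
#' @param n_demes Number of demes D (default 50).
#' @param optimum_slope Change in the optimal phenotype between adjacent
#'   demes, trait units per deme (default 0.4).
#' @param expression_slope Change in the plastic-locus expression multiplier
#'   between adjacent demes, multiplier units per deme (default 0.04).
#' @return An object of class `gradient_spec`: a list with the arguments plus
#'   `midpoint`, the vector `optima` (length D) and the vector `multipliers`
#'   (length D, the unperturbed expression multipliers).
#' @examples
#' g <- build_gradient()
#' g$optima[c(1, 50)]        # -9.8  9.8
#' diff(g$optima[25:26])     # 0.4
#' @export
build_gradient <- function(n_demes = 50L, optimum_slope = 0.4,
                           expression_slope = 0.04) {
  n_demes <- as.integer(n_demes)
  if (length(n_demes) != 1L || is.na(n_demes) || n_demes < 1L)
    stop("`n_demes` must be a single positive integer", call. = FALSE)
  if (!is.finite(optimum_slope) || !is.finite(expression_slope))
    stop("gradient slopes must be finite", call. = FALSE)
  midpoint <- (n_demes + 1) / 2
  pos <- seq_len(n_demes) - midpoint
  structure(
    list(
      n_demes = n_demes,
      optimum_slope = optimum_slope,
      expression_slope = expression_slope,
      midpoint = midpoint,
      optima = optimum_slope * pos,
      multipliers = expression_slope * pos
    ),
    class = "gradient_spec"
  )
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat("Linear gradient:", x$n_demes, "demes\n")
  cat("  optimum slope    :", x$optimum_slope, "trait units/deme",
      sprintf("(range %g to %g)\n", x$optima[1], x$optima[x$n_demes]))
  cat("  expression slope :", x$expression_slope, "multiplier units/deme\n")
  invisible(x)
}

#' Optimum-matching plastic allelic sum
#'
#' The plastic allelic sum for which the reaction norm tracks the gradient of
#' optima exactly: optimum_slope / expression_slope (10 under the defaults).
#' Used to standardize mean plasticity to the optimal reaction norm.
#'
#' @param gradient A [build_gradient()] object.
#' @return A single number, the plastic sum of the optimal reaction norm.
#' @export
optimal_plastic_sum <- function(gradient) {
  stopifnot(inherits(gradient, "gradient_spec"))
  if (gradient$expression_slope == 0)
    stop("expression_slope is 0: the optimal plastic sum is undefined",
         call. = FALSE)
  gradient$optimum_slope / gradient$expression_slope
}
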