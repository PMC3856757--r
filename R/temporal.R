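#' Temporal-heterogeneity specification
#'
#' Describes how the environment fluctuates around the static gradient.
#' Deviations follow a stationary AR(1) process on the trait (optimum) scale,
#'   d_t = rho * d_(t-1) + tau * sqrt(1 - rho^2) * z_t,
#' with z_t independent standard normal innovations, so the marginal standard
#' deviation of the deviation is tau at every rho. Fluctuations can occur
#' before development (displacing the cue the plastic loci respond to),
#' before selection (displacing the optimum selection acts on), or both:
#'
#' * `"none"`: no temporal variation; both stages sit on the gradient.
#' * `"p1"`: change before selection only; the development environment is
#'   fixed at the gradient value.
#' * `"p2"`: change before development only; the selection optimum is fixed.
#' * `"p3"`: change at both stages, with within-generation correlation
#'   `corr_within` between the two innovations. `corr_within = 1` means a
#'   single change carries through the whole life cycle; negative values give
#'   a development cue that points away from the selection optimum.
#'
#' With `synchronized = TRUE` one shared innovation per stage drives every
#' deme, so the whole gradient shifts up or down coherently; otherwise each
#' deme fluctuates independently.
#'
#' @param pattern One of `"none"`, `"p1"`, `"p2"`, `"p3"`.
#' @param tau_pct Standard deviation of the environmental deviation, as a
#'   percentage of the difference in optima at the two ends of the gradient
#'   (19.6 trait units under the defaults). Single-deme runs use the same
#'   19.6-unit base so temporal-only and gradient runs are comparable.
#' @param rho_among Among-generation autocorrelation, in (-1, 1); the model
#'   space explored is -0.75 to 0.75.
#' @param corr_within Within-generation correlation of the development- and
#'   selection-stage innovations, in [-1, 1]; only meaningful for `"p3"`.
#' @param synchronized Share one innovation per stage across all demes?
#' @return An object of class `temporal_spec`.
#' @export
temporal_spec <- function(pattern = c("none", "p1", "p2", "p3"),
                          tau_pct = 0, rho_among = 0, corr_within = 0,
                          synchronized = FALSE) {
  pattern <- match.arg(pattern)
  if (!is.finite(tau_pct) || tau_pct < 0)
    stop("`tau_pct` must be a finite non-negative percentage", call. = FALSE)
  if (!is.finite(rho_among) || abs(rho_among) >= 1)
    stop("`rho_among` must lie strictly inside (-1, 1)", call. = FALSE)
  if (!is.finite(corr_within) || abs(corr_within) > 1)
    stop("`corr_within` must lie in [-1, 1]", call. = FALSE)
  if (corr_within != 0 && pattern != "p3")
    stop("`corr_within` is only meaningful for pattern \"p3\"", call. = FALSE)
  structure(
    list(pattern = pattern, tau_pct = tau_pct, rho_among = rho_among,
         corr_within = corr_within, synchronized = isTRUE(synchronized)),
    class = "temporal_spec"
  )
}

# Reference gradient span used to convert tau_pct to trait units when the
# spatial gradient is degenerate (single deme): 0.4 * 49 = 19.6.
.TAU_REFERENCE_SPAN <- 19.6

#' Temporal deviation scale in trait units
#'
#' Converts the percentage `tau_pct` to trait units. The base is the
#' difference between the optima at the two ends of the gradient; for a
#' single-deme run (where that difference is zero) the default-gradient span
#' of 19.6 trait units is used instead, so the percentage axis means the same
#' thing in temporal-only and spatial runs.
#'
#' @param temporal A [temporal_spec()] object.
#' @param gradient A [build_gradient()] object.
#' @return tau in trait units.
#' @export
tau_units <- function(temporal, gradient) {
  span <- if (gradient$n_demes > 1)
    abs(gradient$optima[gradient$n_demes] - gradient$optima[1])
  else .TAU_REFERENCE_SPAN
  temporal$tau_pct / 100 * span
}

#' Initialize per-deme environment state
#'
#' Creates the mutable environment record carried across generations: the
#' AR(1) deviation at each stage (started at zero, the stationary mean) and
#' the realized development and selection environments on the trait scale.
#'
#' @param gradient A [build_gradient()] object.
#' @param temporal A [temporal_spec()] object.
#' @return An object of class `deme_environment` with fields `dev_env`,
#'   `sel_env` (trait scale, length D), `dev_state`, `sel_state` (the AR(1)
#'   deviations), `tau` (trait units) and the generating specs.
#' @export
env_init <- function(gradient, temporal = temporal_spec("none")) {
  stopifnot(inherits(gradient, "gradient_spec"),
            inherits(temporal, "temporal_spec"))
  zero <- numeric(gradient$n_demes)
  structure(
    list(dev_env = gradient$optima, sel_env = gradient$optima,
         dev_state = zero, sel_state = zero,
         tau = tau_units(temporal, gradient),
         temporal = temporal, gradient = gradient),
    class = "deme_environment"
  )
}

#' Advance the environment by one generation
#'
#' Draws this generation's environmental deviations. For each varying stage
#' the deviation follows the stationary AR(1) recursion (see
#' [temporal_spec()]); the stage environment is the gradient optimum plus the
#' deviation. Under pattern `"p3"` the two stage innovations are bivariate
#' standard normal with correlation `corr_within`; at `corr_within = 1` the
#' development deviation carries through unchanged to selection. Under
#' `synchronized = TRUE` a single innovation per stage is shared by all
#' demes. The development value applies at development and the selection
#' value at selection within the same generation; stages not flagged as
#' varying stay pinned to the gradient.
#'
#' Uses the R global random number stream.
#'
#' @param env A [env_init()] object.
#' @return The updated `deme_environment`.
#' @export
step_temporal <- function(env) {
  spec <- env$temporal
  if (env$tau == 0 || spec$pattern == "none") return(env)
  D <- env$gradient$n_demes
  rho <- spec$rho_among
  innov_sd <- env$tau * sqrt(1 - rho^2)
  draw <- function(n) if (spec$synchronized) rep(rnorm(1L), n) else rnorm(n)

  if (spec$pattern == "p3") {
    z_dev <- draw(D)
    c_w <- spec$corr_within
    z_sel <- c_w * z_dev + sqrt(1 - c_w^2) * draw(D)
    env$dev_state <- rho * env$dev_state + innov_sd * z_dev
    env$sel_state <- rho * env$sel_state + innov_sd * z_sel
  } else if (spec$pattern == "p1") {
    env$sel_state <- rho * env$sel_state + innov_sd * draw(D)
  } else { # p2
    env$dev_state <- rho * env$dev_state + innov_sd * draw(D)
  }
  env$dev_env <- env$gradient$optima + env$dev_state
  env$sel_env <- env$gradient$optima + env$sel_state
  env
}

#' Expression multiplier of the plastic loci
#'
#' The environment-dependent quantity that multiplies plastic allelic values
#' at development. The development-stage environment (trait scale) is mapped
#' to the multiplier scale by the fixed ratio optimum_slope /
#' expression_slope (10 under the defaults), so with no temporal perturbation
#' the multiplier in deme i is exactly expression_slope * (i - midpoint), and
#' a perturbation of the development environment displaces the cue and the
#' optimum consistently.
#'
#' @param env A `deme_environment`.
#' @param deme Deme index (1-based) or vector of indices.
#' @return Multiplier value(s).
#' @export
expression_multiplier <- function(env, deme) {
  g <- env$gradient
  if (any(deme < 1L | deme > g$n_demes))
    stop("deme index out of range [1, ", g$n_demes, "]", call. = FALSE)
  env$dev_env[deme] * (g$expression_slope / g$optimum_slope)
}
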