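#' Dispersal specification
#'
#' Two movement kernels are supported. Under *stepping-stone* dispersal the
#' probability of moving and the distance moved are coupled through one
#' zero-mean Gaussian draw: the displacement is the nearest integer of a
#' Normal(0, kernel_sd) number, clamped to the terminal demes, so raising the
#' kernel SD makes individuals both more likely to move and likely to move
#' farther. Under *island* dispersal each individual moves with a fixed
#' probability and, if it moves, lands on any one of the other demes with
#' equal probability. In both modes the headline `rate` is the per-individual
#' probability of leaving the current deme, which makes the two kernels
#' comparable; dispersal itself is cost-free.
#'
#' @param mode `"stepping_stone"` or `"island"`.
#' @param rate Probability of moving, in [0, 1] ([0, 1) for stepping-stone).
#' @return An object of class `dispersal_spec` with the derived `kernel_sd`
#'   for stepping-stone mode.
#' @export
dispersal_spec <- function(mode = c("stepping_stone", "island"), rate = 0) {
  mode <- match.arg(mode)
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("dispersal `rate` must lie in [0, 1]", call. = FALSE)
  kernel_sd <- if (mode == "stepping_stone") rate_to_kernel_sd(rate) else NA_real_
  structure(list(mode = mode, rate = rate, kernel_sd = kernel_sd),
            class = "dispersal_spec")
}

#' Gaussian kernel SD giving a target move probability
#'
#' For the stepping-stone kernel the displacement is round(Normal(0, s)), so
#' an individual stays put iff the draw lies in (-0.5, 0.5). The s for which
#' the move probability P(|g| >= 0.5) equals `rate` is the closed form
#' s = 0.5 / qnorm(1 - rate/2); rate 0 maps to s = 0 (nobody moves).
#'
#' @param rate Move probability in [0, 1). Rate 1 has no finite s.
#' @return The kernel standard deviation, deme units.
#' @examples
#' rate_to_kernel_sd(0.64)  # ~1.069
#' @export
rate_to_kernel_sd <- function(rate) {
  if (!is.finite(rate) || rate < 0 || rate >= 1)
    stop("stepping-stone `rate` must lie in [0, 1): rate 1 has no finite ",
         "kernel SD", call. = FALSE)
  if (rate == 0) return(0)
  0.5 / qnorm(1 - rate / 2)
}

#' Stepping-stone displacement
#'
#' Moves each individual by the nearest integer of a Normal(0, kernel_sd)
#' draw. Destinations beyond the ends of the gradient are clamped to the
#' terminal demes.
#'
#' Uses the R global random number stream.
#'
#' @param deme Current deme index (vectorized, 1-based).
#' @param kernel_sd Gaussian kernel SD (see [rate_to_kernel_sd()]).
#' @param n_demes Number of demes D.
#' @return New deme indices.
#' @export
stepping_stone_move <- function(deme, kernel_sd, n_demes) {
  if (kernel_sd == 0) return(as.integer(deme))
  step <- as.integer(round(rnorm(length(deme), 0, kernel_sd)))
  pmin.int(pmax.int(deme + step, 1L), as.integer(n_demes))
}

#' Island-model movement
#'
#' With probability `rate` an individual moves; the destination is uniform
#' over the D - 1 other demes.
#'
#' Uses the R global random number stream.
#'
#' @param deme Current deme index (vectorized, 1-based).
#' @param rate Move probability in [0, 1].
#' @param n_demes Number of demes D (>= 2 when rate > 0).
#' @return New deme indices.
#' @export
island_move <- function(deme, rate, n_demes) {
  deme <- as.integer(deme)
  if (rate == 0) return(deme)
  n_demes <- as.integer(n_demes)
  if (n_demes < 2L)
    stop("island dispersal with rate > 0 requires at least 2 demes",
         call. = FALSE)
  n <- length(deme)
  moves <- runif(n) < rate
  if (any(moves)) {
    # uniform over the other demes: draw in 1..D-1 and skip the current deme
    r <- 1L + as.integer(floor(runif(sum(moves)) * (n_demes - 1L)))
    r <- pmin.int(r, n_demes - 1L) # guard against runif() == 1
    deme[moves] <- r + (r >= deme[moves])
  }
  deme
}

# Vectorized dispersal of a whole population under a dispersal_spec.
disperse <- function(pop, spec, n_demes) {
  if (pop_size(pop) == 0L || spec$rate == 0) return(pop)
  pop$deme <- if (spec$mode == "stepping_stone")
    stepping_stone_move(pop$deme, spec$kernel_sd, n_demes)
  else
    island_move(pop$deme, spec$rate, n_demes)
  pop
}
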