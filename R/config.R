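# Run configuration: validation, serialization, sweeps, presets.

.CONFIG_DEFAULTS <- list(
  n_demes = 50L, optimum_slope = 0.4, expression_slope = 0.04,
  pattern = "none", tau_pct = 0, rho_among = 0, corr_within = 0,
  synchronized = FALSE,
  sigma = 2,
  migration = "stepping_stone", dispersal_rate = 0,
  order = "select_first", n_generations = 10000L, deme_capacity = NULL,
  mutation_rate = 0.1, mutation_sd = 0.1,
  master_seed = 1L, n_success = 20L, max_attempts = 60L
)

#' Build and validate a run configuration
#'
#' Bundles every model parameter into one validated object. Defaults are the
#' standard model settings: 50 demes, optimum slope 0.4 and expression slope
#' 0.04 per deme, selection strength sigma = 2, carrying capacity 100 per
#' deme, 10,000 generations, 5 nonplastic + 5 plastic diploid loci,
#' per-allele mutation probability 0.1 with mutational SD 0.1, no temporal
#' variation and no dispersal. A single-deme configuration (temporal
#' variation only) defaults to a capacity of 1000 individuals.
#'
#' Cross-field rules enforced here: `corr_within` requires pattern `"p3"`;
#' dispersal requires more than one deme; stepping-stone dispersal requires
#' rate < 1 (the Gaussian kernel has no finite SD at rate 1).
#'
#' @param ... Named parameters overriding the defaults. Recognized keys:
#'   `n_demes`, `optimum_slope`, `expression_slope`, `pattern`
#'   (`none|p1|p2|p3`), `tau_pct`, `rho_among`, `corr_within`,
#'   `synchronized`, `sigma`, `migration` (`stepping_stone|island`),
#'   `dispersal_rate`, `order` (`select_first|move_first`),
#'   `n_generations`, `deme_capacity`, `mutation_rate`, `mutation_sd`,
#'   `master_seed`, `n_success`, `max_attempts`.
#' @return An object of class `run_config` carrying the scalar parameters
#'   plus the built `gradient`, `temporal` and `dispersal` spec objects.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1L]]))
    user <- user[[1L]]
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, user)

  cfg$n_demes <- as.integer(cfg$n_demes)
  cfg$order <- match.arg(cfg$order, c("select_first", "move_first"))
  cfg$migration <- match.arg(cfg$migration, c("stepping_stone", "island"))
  if (is.null(cfg$deme_capacity))
    cfg$deme_capacity <- if (cfg$n_demes == 1L) 1000L else 100L
  cfg$deme_capacity <- as.integer(cfg$deme_capacity)
  cfg$n_generations <- as.integer(cfg$n_generations)
  if (cfg$n_generations < 1L || cfg$deme_capacity < 1L)
    stop("`n_generations` and `deme_capacity` must be positive",
         call. = FALSE)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1 || cfg$mutation_sd < 0)
    stop("invalid mutation parameters", call. = FALSE)

  gradient <- build_gradient(cfg$n_demes, cfg$optimum_slope,
                             cfg$expression_slope)
  temporal <- temporal_spec(cfg$pattern, cfg$tau_pct, cfg$rho_among,
                            cfg$corr_within, cfg$synchronized)
  if (cfg$dispersal_rate > 0 && cfg$n_demes == 1L)
    stop("dispersal requires more than one deme (`dispersal_rate` > 0 ",
         "with `n_demes` = 1)", call. = FALSE)
  dispersal <- dispersal_spec(cfg$migration, cfg$dispersal_rate)
  if (!is.finite(cfg$sigma) || cfg$sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)

  structure(c(cfg, list(gradient = gradient, temporal = temporal,
                        dispersal = dispersal)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat("  gradient  :", x$n_demes, "demes, optimum slope", x$optimum_slope,
      "\n")
  cat("  temporal  : pattern", x$pattern, "tau", x$tau_pct,
      "% rho", x$rho_among, "corr_within", x$corr_within,
      if (x$synchronized) "(synchronized)" else "", "\n")
  cat("  dispersal :", x$migration, "rate", x$dispersal_rate, "\n")
  cat("  life cycle:", x$order, ",", x$n_generations, "generations,",
      "capacity", x$deme_capacity, "\n")
  invisible(x)
}

# Scalar view of a config (drops the derived spec objects).
config_fields <- function(config) {
  config[intersect(names(.CONFIG_DEFAULTS), names(config))]
}

#' Read a run configuration from a JSON file
#'
#' The file holds a flat JSON object of configuration keys (see
#' [run_config()]); unknown keys, type mismatches and cross-field violations
#' raise descriptive errors. An empty object yields the full default
#' configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) && is.null(names(raw)))
    stop("config file must hold a JSON object of named keys", call. = FALSE)
  run_config(as.list(raw))
}

#' Write a run configuration to a JSON file
#'
#' Serializes the scalar fields of a config so that
#' `load_config(write_config(cfg, path))` round-trips.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(config_fields(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Expand a parameter grid into run configurations
#'
#' Takes named axes (each a finite vector of values for one configuration
#' key) and returns the Cartesian product as a list of validated configs,
#' each with a distinct derived master seed so replicate streams never
#' collide across grid cells. Duplicate cells are dropped with a warning.
#'
#' @param axes Named list of value vectors, e.g.
#'   `list(dispersal_rate = c(0.05, 0.64), tau_pct = c(0, 10, 30))`.
#' @param base Baseline configuration the axes override (default
#'   `run_config()` defaults).
#' @param master_seed Seed from which each cell's `master_seed` is derived.
#' @return A list of `run_config` objects, with the grid cell stored as
#'   attribute `"cell"` on each.
#' @export
expand_sweep <- function(axes, base = list(), master_seed = 1L) {
  if (length(axes) == 0L || is.null(names(axes)) || any(names(axes) == ""))
    stop("`axes` must be a named list of value vectors", call. = FALSE)
  if (any(lengths(axes) == 0L))
    stop("empty sweep axis: ", paste(names(axes)[lengths(axes) == 0L],
                                     collapse = ", "), call. = FALSE)
  grid <- expand.grid(axes, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  dup <- duplicated(grid)
  if (any(dup)) {
    warning(sum(dup), " duplicate grid cell(s) dropped", call. = FALSE)
    grid <- grid[!dup, , drop = FALSE]
  }
  if (inherits(base, "run_config")) base <- config_fields(base)
  lapply(seq_len(nrow(grid)), function(i) {
    cell <- as.list(grid[i, , drop = FALSE])
    cfg <- utils::modifyList(base, cell)
    cfg$master_seed <- child_seed(master_seed, 7919L * i)
    out <- run_config(cfg)
    attr(out, "cell") <- cell
    out
  })
}

# Figure-style experiment presets: the parameter combinations behind the
# qualitative headline results, at full scale. Axes varied in the original
# surfaces are fixed here at a representative point; override via `...` in
# preset_config().
.PRESETS <- list(
  # single-deme, temporal-only runs (capacity 1000)
  fig1a = list(n_demes = 1L, pattern = "p3", corr_within = 1, tau_pct = 20,
               dispersal_rate = 0),
  fig1b = list(n_demes = 1L, pattern = "p3", corr_within = 0, tau_pct = 10,
               dispersal_rate = 0),
  fig1c = list(n_demes = 1L, pattern = "p3", corr_within = -1, tau_pct = 20,
               dispersal_rate = 0),
  # gradient runs, change before selection only
  fig2a = list(pattern = "p1", tau_pct = 10, dispersal_rate = 0.64,
               order = "select_first"),
  fig2b = list(pattern = "p1", tau_pct = 30, dispersal_rate = 0.64,
               order = "move_first"),
  fig2d = list(pattern = "p1", tau_pct = 30, rho_among = -0.75,
               dispersal_rate = 0.64, order = "move_first"),
  # change before development carried through to selection
  fig3a = list(pattern = "p3", corr_within = 1, tau_pct = 10,
               dispersal_rate = 0.64, order = "select_first"),
  fig3b = list(pattern = "p3", corr_within = 1, tau_pct = 10,
               dispersal_rate = 0.64, order = "move_first"),
  # uncorrelated change at both stages
  fig4a = list(pattern = "p3", corr_within = 0, tau_pct = 20,
               dispersal_rate = 0.64, order = "select_first"),
  fig4d = list(pattern = "p3", corr_within = -0.75, tau_pct = 20,
               dispersal_rate = 0.64, order = "move_first"),
  # spatial variation only: migration-pattern contrast at low dispersal
  fig5_stepping = list(migration = "stepping_stone", dispersal_rate = 0.05,
                       order = "select_first"),
  fig5_island = list(migration = "island", dispersal_rate = 0.05,
                     order = "select_first")
)

#' Named experiment presets
#'
#' Ready-made configurations for the headline experiment families: temporal
#' variation only in a single deme (`fig1a`-`fig1c`), change before
#' selection on the gradient (`fig2a`, `fig2b`, `fig2d`), change before
#' development carried through to selection (`fig3a`, `fig3b`), uncorrelated
#' or partially correlated change at both stages (`fig4a`, `fig4d`), and the
#' island versus stepping-stone contrast (`fig5_stepping`, `fig5_island`).
#'
#' @param name Preset name; see Details. `preset_names()` lists them.
#' @param ... Overrides applied on top of the preset (e.g. a shorter
#'   `n_generations` for scaled-down runs).
#' @return A [run_config()].
#' @export
preset_config <- function(name, ...) {
  if (!name %in% names(.PRESETS))
    stop("unknown preset \"", name, "\"; available: ",
         paste(names(.PRESETS), collapse = ", "), call. = FALSE)
  run_config(utils::modifyList(.PRESETS[[name]], list(...)))
}

#' @rdname preset_config
#' @export
preset_names <- function() names(.PRESETS)
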