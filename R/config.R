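#' Simulation configuration
#'
#' Builds and validates the full parameter set for one simulated survey of a
#' closed population with a true 1:1 sex ratio. The population holds
#' `density_multiplier * grid_resolution^2` individuals placed on a bounded
#' `grid_resolution` x `grid_resolution` lattice, half male and half female.
#' Males relocate each time step with probability `male_move_prob`; the female
#' movement probability is always the complement `1 - male_move_prob` and is
#' never stored independently, so a single parameter spans the whole range of
#' movement asymmetry (0.5 means no sex difference).
#'
#' @param grid_resolution Positive integer `N`; the domain is `N x N` cells.
#' @param density_multiplier Positive integer; population size is
#'   `density_multiplier * N^2` (must come out even so the sexes split
#'   equally).
#' @param male_move_prob Per-step probability in `[0, 1]` that a male moves to
#'   another cell. Females move with probability `1 - male_move_prob`.
#' @param male_detectability,female_detectability Per-encounter probabilities
#'   in `[0, 1]` that an active-search observer records an individual of that
#'   sex. Passive traps ignore detectability by construction.
#' @param passive_effort Fraction in `(0, 1]` of the grid resolution converted
#'   into the number of fixed trap transects (`round(passive_effort * N)`,
#'   minimum 1).
#' @param burn_in_steps Non-negative integer; movement-only steps run before
#'   sampling so the spatial distribution reflects movement behaviour rather
#'   than the uniform initial placement.
#' @param sampling_days Positive integer; each sampling day is one time step
#'   with movement, a trap check, and one active-search transect.
#' @param replicates Positive integer; independent repeats of one parameter
#'   combination.
#' @param alpha Significance level of the chi-square sex-ratio test.
#' @param seed Integer base RNG seed; replicate `i` runs with seed
#'   `seed + i` so replicates are independently reproducible.
#'
#' @return An object of class `sr_config`: a validated named list with the
#'   fields above plus the derived `female_move_prob` and population size `n`.
#' @examples
#' cfg <- sim_config(grid_resolution = 10, sampling_days = 20)
#' cfg$n # 400 individuals
#' @export
sim_config <- function(grid_resolution = 20L,
                       density_multiplier = 4L,
                       male_move_prob = 0.5,
                       male_detectability = 0.5,
                       female_detectability = 0.5,
                       passive_effort = 0.10,
                       burn_in_steps = 100L,
                       sampling_days = 100L,
                       replicates = 100L,
                       alpha = 0.05,
                       seed = 1L) {
  cfg <- list(
    grid_resolution = as.integer(grid_resolution),
    density_multiplier = as.integer(density_multiplier),
    male_move_prob = as.numeric(male_move_prob),
    male_detectability = as.numeric(male_detectability),
    female_detectability = as.numeric(female_detectability),
    passive_effort = as.numeric(passive_effort),
    burn_in_steps = as.integer(burn_in_steps),
    sampling_days = as.integer(sampling_days),
    replicates = as.integer(replicates),
    alpha = as.numeric(alpha),
    seed = as.integer(seed)
  )
  class(cfg) <- "sr_config"
  validate_config(cfg)
}

#' @rdname sim_config
#' @param config An `sr_config` object (or a plain named list with the same
#'   fields) to validate.
#' @export
validate_config <- function(config) {
  stop_if <- function(bad, field, msg) {
    if (bad) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  n_scalar <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)

  stop_if(!n_scalar(config$grid_resolution) || config$grid_resolution < 1,
          "grid_resolution", "must be a positive integer")
  stop_if(!n_scalar(config$density_multiplier) || config$density_multiplier < 1,
          "density_multiplier", "must be a positive integer")
  for (f in c("male_move_prob", "male_detectability", "female_detectability",
              "alpha")) {
    stop_if(!n_scalar(config[[f]]) || config[[f]] < 0 || config[[f]] > 1,
            f, "must be a probability in [0, 1]")
  }
  stop_if(!n_scalar(config$passive_effort) || config$passive_effort <= 0 ||
            config$passive_effort > 1,
          "passive_effort", "must lie in (0, 1]")
  stop_if(!n_scalar(config$burn_in_steps) || config$burn_in_steps < 0,
          "burn_in_steps", "must be a non-negative integer")
  stop_if(!n_scalar(config$sampling_days) || config$sampling_days < 0,
          "sampling_days", "must be a non-negative integer")
  stop_if(!n_scalar(config$replicates) || config$replicates < 1,
          "replicates", "must be a positive integer")
  stop_if(!n_scalar(config$seed), "seed", "must be an integer")

  n <- config$density_multiplier * config$grid_resolution^2
  stop_if(n %% 2 != 0, "density_multiplier",
          paste0("population size ", n,
                 " is odd; the sexes cannot split equally"))

  n_transects <- round_half_up(config$passive_effort * config$grid_resolution)
  stop_if(max(1L, n_transects) > config$grid_resolution, "passive_effort",
          "requests more transects than there are rows")

  config$female_move_prob <- 1 - config$male_move_prob
  config$n <- as.integer(n)
  config
}

#' @export
print.sr_config <- function(x, ...) {
  cat("Sex-ratio sampling simulation configuration\n")
  cat(sprintf("  grid: %d x %d cells, %d individuals (%d per sex)\n",
              x$grid_resolution, x$grid_resolution, x$n, x$n %/% 2L))
  cat(sprintf("  movement: males %.2f, females %.2f per step\n",
              x$male_move_prob, x$female_move_prob))
  cat(sprintf("  detectability: males %.2f, females %.2f\n",
              x$male_detectability, x$female_detectability))
  cat(sprintf("  passive effort %.2f (%d transects), %d sampling days, %d burn-in steps\n",
              x$passive_effort,
              n_passive_transects(x), x$sampling_days, x$burn_in_steps))
  cat(sprintf("  %d replicates, alpha = %.3f, seed = %d\n",
              x$replicates, x$alpha, x$seed))
  invisible(x)
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) as.integer(floor(x + 0.5))

n_passive_transects <- function(config) {
  max(1L, round_half_up(config$passive_effort * config$grid_resolution))
}

#' Read or write a simulation configuration file
#'
#' Configurations are flat YAML key-value files whose keys match the
#' [sim_config()] arguments. Unknown keys are rejected so that typos do not
#' silently fall back to defaults; omitted keys take the documented defaults.
#'
#' @param path File path of the YAML configuration.
#' @return `load_config()` returns a validated `sr_config`; `save_config()`
#'   writes the file and returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' save_config(sim_config(grid_resolution = 10, seed = 7), path)
#' identical(load_config(path), sim_config(grid_resolution = 10, seed = 7))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop("configuration must be a flat named key-value mapping")
  }
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}

#' @rdname load_config
#' @param config A validated `sr_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sr_config"))
  keep <- names(formals(sim_config))
  yaml::write_yaml(config[keep], path)
  invisible(path)
}
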