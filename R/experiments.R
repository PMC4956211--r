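#' Run one full replicate
#'
#' The complete pipeline for a single replicate: seed the RNG, place the
#' population, build the trap layout, run the movement-only burn-in, run the
#' sampling phase (movement, trap checks and one active transect per day),
#' and classify both methods' estimated sex ratios. Each replicate runs on
#' its own RNG stream seeded as `config$seed + replicate_index`, so
#' replicates are independently reproducible and order-independent.
#'
#' @param config A validated [sim_config()].
#' @param replicate_index Positive integer identifying the replicate.
#' @param kernel Optional precomputed [build_distance_kernel()] for
#'   `config$grid_resolution`; built on the fly when omitted. Precomputing
#'   gives identical results and saves time across replicates.
#' @return An `sr_run_result` (see [classify_run()]), with the replicate
#'   index attached as attribute `replicate`.
#' @examples
#' cfg <- sim_config(grid_resolution = 5, burn_in_steps = 10,
#'                   sampling_days = 10, seed = 42)
#' run_replicate(cfg, 1)
#' @export
run_replicate <- function(config, replicate_index = 1L, kernel = NULL) {
  config <- validate_config(config)
  if (is.null(kernel)) kernel <- build_distance_kernel(config$grid_resolution)
  set.seed(config$seed + as.integer(replicate_index))
  pop <- init_population(config)
  layout <- build_trap_layout(config)
  pop <- run_burn_in(pop, kernel, config)
  phase <- run_sampling_phase(pop, kernel, layout, config)
  res <- classify_run(phase$log, phase$population, config$alpha)
  attr(res, "replicate") <- as.integer(replicate_index)
  res
}

#' Run all replicates of one parameter combination
#'
#' @inheritParams run_replicate
#' @return An `sr_sweep_record` (one aggregated row; see
#'   [aggregate_replicates()]).
#' @export
run_combination <- function(config, kernel = NULL) {
  config <- validate_config(config)
  if (is.null(kernel)) kernel <- build_distance_kernel(config$grid_resolution)
  results <- lapply(seq_len(config$replicates), function(i) {
    run_replicate(config, i, kernel)
  })
  aggregate_replicates(results, config)
}

# Offset between the seed blocks of successive parameter combinations;
# leaves room for far more replicates than any sweep uses.
.combo_seed_stride <- 100000L

#' Single-parameter sensitivity sweeps
#'
#' Runs the six sensitivity experiments in which one parameter varies while
#' all others stay at the baseline configuration:
#' \describe{
#'   \item{`grid_size`}{grid resolution 10 to 55 in steps of 5;}
#'   \item{`sampling_days`}{35 to 350 days in steps of 35;}
#'   \item{`movement`}{male movement probability 0.5 to 0.95 in steps of
#'     0.05 (females always move with the complement);}
#'   \item{`passive_effort`}{0.10 to 0.55 in steps of 0.05;}
#'   \item{`detectability_equal`}{both sexes' detectability equal, 0.1 to
#'     1.0 in steps of 0.1;}
#'   \item{`detectability_asymmetric`}{male and female detectability summing
#'     to 1, from (0.1, 0.9) to (0.9, 0.1) in steps of 0.1.}
#' }
#' Combination `k` of a sweep runs with base seed
#' `config$seed + (k - 1) * 100000`, so a sweep re-run with the same seed is
#' bit-identical and individual combinations can be reproduced in isolation.
#'
#' @param sweep Which parameter to vary (see above).
#' @param config Baseline [sim_config()]; its `replicates`, `seed` and all
#'   non-varied parameters are used as-is.
#' @param values Optional custom value grid replacing the default. For
#'   `detectability_asymmetric`, a two-column matrix or data frame of
#'   (male, female) detectabilities.
#' @return An `sr_sweep_table`: a data frame with one [aggregate_replicates()]
#'   row per grid value, in the sweep-table schema.
#' @examples
#' \donttest{
#' cfg <- sim_config(grid_resolution = 10, burn_in_steps = 20,
#'                   sampling_days = 20, replicates = 5, seed = 7)
#' run_sensitivity_sweep("movement", cfg, values = c(0.5, 0.9))
#' }
#' @export
run_sensitivity_sweep <- function(sweep = c("grid_size", "sampling_days",
                                            "movement", "passive_effort",
                                            "detectability_equal",
                                            "detectability_asymmetric"),
                                  config = sim_config(),
                                  values = NULL) {
  sweep <- match.arg(sweep)
  config <- validate_config(config)
  if (is.null(values)) values <- default_sweep_values(sweep)

  configs <- if (sweep == "detectability_asymmetric") {
    values <- as.matrix(values)
    stopifnot(ncol(values) == 2)
    lapply(seq_len(nrow(values)), function(i) {
      modify_config(config, male_detectability = values[i, 1],
                    female_detectability = values[i, 2])
    })
  } else {
    field <- switch(sweep,
                    grid_size = "grid_resolution",
                    sampling_days = "sampling_days",
                    movement = "male_move_prob",
                    passive_effort = "passive_effort",
                    detectability_equal = NULL)
    lapply(values, function(v) {
      if (sweep == "detectability_equal") {
        modify_config(config, male_detectability = v, female_detectability = v)
      } else {
        args <- stats::setNames(list(v), field)
        do.call(modify_config, c(list(config), args))
      }
    })
  }
  run_config_grid(configs, config$seed)
}

#' Effort-by-asymmetry interaction sweeps
#'
#' Re-runs the sampling-days or passive-effort sweep under fixed asymmetry
#' scenarios: four movement scenarios (male movement probability 0.6, 0.7,
#' 0.8, 0.9, females with the complement) or four detectability scenarios
#' ((0.1, 0.9), (0.2, 0.8), (0.3, 0.7), (0.4, 0.6) for males and females).
#' The result covers the full cross grid, one sweep-table row per
#' (scenario, sweep value) pair.
#'
#' @param vary Which effort axis to sweep: `"sampling_days"` (35 to 350 by
#'   35) or `"passive_effort"` (0.10 to 0.55 by 0.05).
#' @param scenarios Which asymmetry the scenarios impose: `"movement"` or
#'   `"detectability"`.
#' @param config Baseline [sim_config()].
#' @param values Optional custom grid for the swept effort axis.
#' @param scenario_values Optional custom scenario set: a numeric vector of
#'   male movement probabilities, or a two-column matrix of (male, female)
#'   detectabilities.
#' @return An `sr_sweep_table` data frame over the cross grid.
#' @export
run_interaction_sweep <- function(vary = c("sampling_days", "passive_effort"),
                                  scenarios = c("movement", "detectability"),
                                  config = sim_config(),
                                  values = NULL,
                                  scenario_values = NULL) {
  vary <- match.arg(vary)
  scenarios <- match.arg(scenarios)
  config <- validate_config(config)
  if (is.null(values)) values <- default_sweep_values(vary)
  if (is.null(scenario_values)) {
    scenario_values <- if (scenarios == "movement") {
      c(0.6, 0.7, 0.8, 0.9)
    } else {
      cbind(male = c(0.1, 0.2, 0.3, 0.4), female = c(0.9, 0.8, 0.7, 0.6))
    }
  }

  scenario_configs <- if (scenarios == "movement") {
    lapply(scenario_values, function(m) modify_config(config, male_move_prob = m))
  } else {
    sv <- as.matrix(scenario_values)
    lapply(seq_len(nrow(sv)), function(i) {
      modify_config(config, male_detectability = sv[i, 1],
                    female_detectability = sv[i, 2])
    })
  }
  configs <- unlist(lapply(scenario_configs, function(sc) {
    lapply(values, function(v) {
      args <- stats::setNames(list(v), vary)
      do.call(modify_config, c(list(sc), args))
    })
  }), recursive = FALSE)
  run_config_grid(configs, config$seed)
}

#' @rdname run_sensitivity_sweep
#' @export
default_sweep_values <- function(sweep) {
  switch(sweep,
         grid_size = seq(10L, 55L, by = 5L),
         sampling_days = seq(35L, 350L, by = 35L),
         movement = seq(0.5, 0.95, by = 0.05),
         passive_effort = seq(0.10, 0.55, by = 0.05),
         detectability_equal = seq(0.1, 1.0, by = 0.1),
         detectability_asymmetric =
           cbind(male = seq(0.1, 0.9, by = 0.1),
                 female = seq(0.9, 0.1, by = -0.1)),
         stop("unknown sweep: ", sweep))
}

modify_config <- function(config, ...) {
  changes <- list(...)
  for (nm in names(changes)) config[[nm]] <- changes[[nm]]
  validate_config(config)
}

# Runs a list of configurations (one per parameter combination), assigning
# each its own seed block and reusing the distance kernel across consecutive
# combinations that share a grid size.
run_config_grid <- function(configs, base_seed) {
  kernel <- NULL
  records <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    cfg$seed <- as.integer(base_seed + (k - 1L) * .combo_seed_stride)
    if (is.null(kernel) || kernel$N != cfg$grid_resolution) {
      kernel <- build_distance_kernel(cfg$grid_resolution)
    }
    records[[k]] <- run_combination(cfg, kernel)
  }
  tab <- do.call(rbind, records)
  class(tab) <- c("sr_sweep_table", "data.frame")
  attr(tab, "seed") <- as.integer(base_seed)
  tab
}
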