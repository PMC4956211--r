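#' Advance the population one movement step
#'
#' Every individual independently decides to move with its sex's per-step
#' probability (males: `male_move_prob`; females: the complement). Movers draw
#' a destination from the inverse-distance kernel row of their current cell
#' and relocate; non-movers stay where they are. Exactly the movers change
#' cells, and the per-individual "moved this step" mask is returned because
#' passive traps capture on arrival only.
#'
#' @param pop An `sr_population`.
#' @param kernel An `sr_kernel` built over the same grid size.
#' @param config A validated [sim_config()].
#' @return A list with `population` (positions updated) and `moved`
#'   (logical vector, one entry per individual).
#' @examples
#' set.seed(1)
#' cfg <- sim_config(grid_resolution = 5)
#' pop <- init_population(cfg)
#' k <- build_distance_kernel(5)
#' st <- step_movement(pop, k, cfg)
#' mean(st$moved) # about 0.5 when both sexes move with probability 0.5
#' @export
step_movement <- function(pop, kernel, config) {
  stopifnot(inherits(pop, "sr_population"), inherits(kernel, "sr_kernel"))
  if (pop$N != kernel$N) {
    stop("population and kernel were built over different grid sizes")
  }
  st <- cpp_step_movement(pop$cell, pop$male,
                          config$male_move_prob, config$female_move_prob,
                          kernel$cum)
  pop$cell <- st$cell
  list(population = pop, moved = st$moved)
}

#' Run the pre-sampling burn-in
#'
#' Applies [step_movement()] `burn_in_steps` times with no sampling, so that
#' individuals spread over the space according to their movement behaviour
#' instead of the uniform initial placement. Population size and identities
#' are unchanged.
#'
#' @inheritParams step_movement
#' @return The population after the burn-in.
#' @export
run_burn_in <- function(pop, kernel, config) {
  for (i in seq_len(config$burn_in_steps)) {
    pop <- step_movement(pop, kernel, config)$population
  }
  pop
}
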