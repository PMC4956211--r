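#' Initialise a population with a true 1:1 sex ratio
#'
#' Places `n = density_multiplier * N^2` individuals independently and
#' uniformly over the `N^2` cells of the domain, exactly half male and half
#' female. Individuals carry stable integer identities (`1..n`) for the whole
#' replicate, which is what gives the survey its mark-recapture semantics:
#' a captured individual is recognised, never removed, and counted at most
#' once per method. Several individuals may share a cell; there is no
#' exclusion constraint.
#'
#' Uses the current RNG state; call `set.seed()` (or go through
#' [run_replicate()], which seeds per replicate) for reproducibility.
#'
#' @param config A validated [sim_config()].
#' @return An object of class `sr_population`: a list with grid size `N`,
#'   population size `n`, integer vector `id`, logical vector `male`, and
#'   integer vector `cell` of current 1-based cell indices.
#' @examples
#' set.seed(1)
#' pop <- init_population(sim_config(grid_resolution = 10))
#' table(pop$male) # 200 FALSE, 200 TRUE
#' @export
init_population <- function(config) {
  config <- validate_config(config)
  N <- config$grid_resolution
  n <- config$n
  pop <- list(
    N = N,
    n = n,
    id = seq_len(n),
    male = rep(c(TRUE, FALSE), each = n %/% 2L),
    cell = sample.int(N * N, n, replace = TRUE)
  )
  class(pop) <- "sr_population"
  pop
}

#' @export
print.sr_population <- function(x, ...) {
  cat(sprintf("Population of %d individuals (%d males, %d females) on a %d x %d grid\n",
              x$n, sum(x$male), x$n - sum(x$male), x$N, x$N))
  invisible(x)
}

#' @export
as.data.frame.sr_population <- function(x, ...) {
  rc <- cell_coords(x$cell, x$N)
  data.frame(id = x$id,
             sex = ifelse(x$male, "male", "female"),
             row = rc[, "row"],
             col = rc[, "col"])
}
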