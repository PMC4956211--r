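#' Transects and trap layouts
#'
#' Both sampling methods work on transects: contiguous runs of
#' `floor(N / 2)` cells along one row, starting at a column drawn from
#' `1..floor(N / 2)` so the whole transect always fits inside the domain.
#'
#' The passive method fixes `round(passive_effort * N)` transects (minimum 1)
#' for the whole survey, drawn on distinct rows, and places a trap station on
#' alternating cells starting with the transect's first cell — giving
#' `ceiling(length / 2)` stations per transect. Any individual whose movement
#' step ends in a station cell is recorded.
#'
#' The active method draws one fresh transect per sampling day and searches
#' every cell of it (no alternating gaps); each individual present is
#' recorded with its sex's detectability.
#'
#' @param config A validated [sim_config()].
#' @return `build_trap_layout()` returns an `sr_trap_layout`: a list with
#'   `N`, a data frame `transects` (`row`, `start_col`, `length`), the
#'   integer vector `trap_cells`, and a logical lookup of length `N^2`.
#'   `new_transect()` / `choose_active_transect()` return an `sr_transect`
#'   list with `row`, `start_col`, `length` and `cells`.
#' @examples
#' set.seed(1)
#' layout <- build_trap_layout(sim_config(grid_resolution = 8, passive_effort = 0.1))
#' nrow(layout$transects)    # 1 transect on an 8 x 8 grid at 10% effort
#' length(layout$trap_cells) # 2 stations (alternating cells of a 4-cell transect)
#' @export
build_trap_layout <- function(config) {
  config <- validate_config(config)
  N <- config$grid_resolution
  if (N < 2L) stop("trap transects need a grid of at least 2 x 2 cells")
  n_tr <- n_passive_transects(config)
  if (n_tr > N) stop("passive effort requests more transects than rows")
  len <- N %/% 2L
  rows <- sample.int(N, n_tr) # distinct rows: effort maps to coverage
  starts <- sample.int(len, n_tr, replace = TRUE)
  trap_cells <- unlist(lapply(seq_len(n_tr), function(i) {
    cols <- seq.int(starts[i], by = 2L, length.out = (len + 1L) %/% 2L)
    cell_index(rows[i], cols, N)
  }))
  lookup <- logical(N * N)
  lookup[trap_cells] <- TRUE
  structure(list(N = N,
                 transects = data.frame(row = rows, start_col = starts,
                                        length = len),
                 trap_cells = as.integer(trap_cells),
                 lookup = lookup),
            class = "sr_trap_layout")
}

#' @rdname build_trap_layout
#' @param row,start_col 1-based transect coordinates.
#' @param N Grid resolution.
#' @export
new_transect <- function(row, start_col, N) {
  len <- N %/% 2L
  stopifnot(row >= 1L, row <= N, start_col >= 1L, start_col <= len)
  cols <- seq.int(start_col, length.out = len)
  structure(list(row = as.integer(row), start_col = as.integer(start_col),
                 length = len, cells = cell_index(row, cols, N)),
            class = "sr_transect")
}

#' @rdname build_trap_layout
#' @export
choose_active_transect <- function(config) {
  N <- config$grid_resolution
  if (N < 2L) stop("active transects need a grid of at least 2 x 2 cells")
  len <- N %/% 2L
  new_transect(sample.int(N, 1L), sample.int(len, 1L), N)
}

#' Capture log with mark-recapture semantics
#'
#' Tracks which individuals have ever been recorded by each method as logical
#' membership vectors, so each individual is counted at most once per method
#' no matter how often it is re-captured. The two methods tally
#' independently; an individual may appear in both.
#'
#' @param pop An `sr_population`.
#' @return An `sr_capture_log`: list of logical vectors `passive` and
#'   `active`, one entry per individual.
#' @export
new_capture_log <- function(pop) {
  structure(list(passive = logical(pop$n), active = logical(pop$n)),
            class = "sr_capture_log")
}

#' Capture events of one sampling day
#'
#' `apply_passive_capture()` records every individual whose movement step
#' just ended inside a trap cell (capture on arrival: an individual sitting
#' still on a station is not re-evaluated). `apply_active_capture()` records
#' each individual currently on the day's search transect with its sex's
#' detectability. Neither removes anyone from the population.
#'
#' @param pop An `sr_population` (positions after the day's movement).
#' @param moved Logical mask returned by [step_movement()] for this step.
#' @param layout An `sr_trap_layout`.
#' @param transect The day's `sr_transect`.
#' @param config A validated [sim_config()].
#' @param log An `sr_capture_log`.
#' @return The updated capture log.
#' @export
apply_passive_capture <- function(pop, moved, layout, log) {
  log$passive[moved & layout$lookup[pop$cell]] <- TRUE
  log
}

#' @rdname apply_passive_capture
#' @export
apply_active_capture <- function(pop, transect, config, log) {
  rc_row <- (pop$cell - 1L) %% pop$N + 1L
  rc_col <- (pop$cell - 1L) %/% pop$N + 1L
  on_transect <- rc_row == transect$row &
    rc_col >= transect$start_col &
    rc_col < transect$start_col + transect$length
  idx <- which(on_transect)
  if (length(idx) > 0) {
    det <- ifelse(pop$male[idx], config$male_detectability,
                  config$female_detectability)
    log$active[idx[stats::runif(length(idx)) < det]] <- TRUE
  }
  log
}

#' Run the sampling phase of one replicate
#'
#' After burn-in, each sampling day is one time step: (1) everybody moves,
#' (2) arrivals into trap cells are logged, (3) one active-search transect is
#' drawn and searched. Both methods observe the same population trajectory.
#'
#' @inheritParams apply_passive_capture
#' @param kernel An `sr_kernel` over the same grid.
#' @return A list with the final `log` (`sr_capture_log`) and `population`.
#' @export
run_sampling_phase <- function(pop, kernel, layout, config) {
  log <- new_capture_log(pop)
  for (day in seq_len(config$sampling_days)) {
    st <- step_movement(pop, kernel, config)
    pop <- st$population
    log <- apply_passive_capture(pop, st$moved, layout, log)
    transect <- choose_active_transect(config)
    log <- apply_active_capture(pop, transect, config, log)
  }
  list(log = log, population = pop)
}
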