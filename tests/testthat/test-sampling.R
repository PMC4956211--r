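test_that("trap layout geometry follows effort, length and alternation rules", {
  set.seed(21)
  # 8 x 8 grid at 10% effort: round(0.8) -> minimum of 1 transect of length
  # 4 holding 2 alternating stations
  layout <- build_trap_layout(sim_config(grid_resolution = 8,
                                         passive_effort = 0.10))
  expect_equal(nrow(layout$transects), 1L)
  expect_equal(layout$transects$length, 4L)
  expect_equal(length(layout$trap_cells), 2L)
  rc <- cell_coords(layout$trap_cells, 8)
  expect_equal(unique(rc[, "row"]), layout$transects$row)
  expect_equal(diff(sort(rc[, "col"])), 2L) # trap, gap, trap

  # 10 x 10 at 50%: 5 transects of length 5 with 3 stations, distinct rows
  layout <- build_trap_layout(sim_config(grid_resolution = 10,
                                         passive_effort = 0.50))
  expect_equal(nrow(layout$transects), 5L)
  expect_true(all(layout$transects$length == 5L))
  expect_equal(length(layout$trap_cells), 15L)
  expect_equal(anyDuplicated(layout$transects$row), 0L)

  # degenerate smallest case: 2 x 2 at full effort, two single-cell transects
  layout <- build_trap_layout(sim_config(grid_resolution = 2,
                                         passive_effort = 1.0))
  expect_equal(nrow(layout$transects), 2L)
  expect_true(all(layout$transects$length == 1L))
  expect_equal(length(layout$trap_cells), 2L)
})

test_that("transect cells always lie inside the domain", {
  set.seed(22)
  for (N in c(2, 5, 8, 13)) {
    layout <- build_trap_layout(sim_config(grid_resolution = N,
                                           passive_effort = 1.0))
    expect_true(all(layout$trap_cells >= 1 & layout$trap_cells <= N^2))
    tr <- choose_active_transect(sim_config(grid_resolution = N))
    expect_true(all(tr$cells >= 1 & tr$cells <= N^2))
    expect_equal(length(tr$cells), N %/% 2L)
    rc <- cell_coords(tr$cells, N)
    expect_true(all(rc[, "row"] == tr$row))
    expect_equal(unname(diff(rc[, "col"])), rep(1, max(tr$length - 1L, 0L)))
  }
})

test_that("a fresh active transect is drawn daily with uniform rows", {
  set.seed(23)
  cfg <- sim_config(grid_resolution = 10)
  rows <- replicate(5000, choose_active_transect(cfg)$row)
  expect_gt(length(unique(rows[1:10])), 1L) # transects re-drawn, not fixed
  expect_gt(stats::chisq.test(tabulate(rows, 10))$p.value, 0.001)
})

test_that("passive capture triggers on arrival only and never removes", {
  N <- 5
  cfg <- sim_config(grid_resolution = N)
  layout <- structure(list(
    N = N,
    transects = data.frame(row = 1L, start_col = 1L, length = 2L),
    trap_cells = cell_index(1, 1, N),
    lookup = replace(logical(N^2), cell_index(1, 1, N), TRUE)
  ), class = "sr_trap_layout")
  pop <- fixed_population(N, c(cell_index(1, 1, N), cell_index(1, 1, N),
                               cell_index(3, 3, N)),
                          male = c(TRUE, FALSE, TRUE))
  log <- new_capture_log(pop)
  # individual 1 arrived on the trap this step; individual 2 sits still on it
  log <- apply_passive_capture(pop, c(TRUE, FALSE, TRUE), layout, log)
  expect_identical(which(log$passive), 1L)
  expect_equal(pop$n, 3L) # recognition, not removal
  # no arrivals into trap cells: log unchanged
  log2 <- apply_passive_capture(pop, c(FALSE, FALSE, TRUE), layout, log)
  expect_identical(log2$passive, log$passive)
})

test_that("active detection applies the sex-specific probabilities", {
  N <- 6
  tr <- new_transect(2, 1, N)
  n_per_sex <- 5000
  pop <- fixed_population(N, rep(tr$cells[1], 2 * n_per_sex),
                          male = rep(c(TRUE, FALSE), each = n_per_sex))

  # certain detection captures everybody on the transect
  cfg <- sim_config(grid_resolution = N, male_detectability = 1,
                    female_detectability = 1)
  log <- apply_active_capture(pop, tr, cfg, new_capture_log(pop))
  expect_true(all(log$active))

  # zero male detectability never captures a male
  set.seed(24)
  cfg <- sim_config(grid_resolution = N, male_detectability = 0,
                    female_detectability = 0.5)
  log <- apply_active_capture(pop, tr, cfg, new_capture_log(pop))
  expect_true(!any(log$active[pop$male]))
  expect_gt(sum(log$active[!pop$male]), 0)

  # (0.1, 0.9): per-sex frequencies within 3 Monte-Carlo standard errors
  set.seed(25)
  cfg <- sim_config(grid_resolution = N, male_detectability = 0.1,
                    female_detectability = 0.9)
  log <- apply_active_capture(pop, tr, cfg, new_capture_log(pop))
  se1 <- sqrt(0.1 * 0.9 / n_per_sex)
  expect_lt(abs(mean(log$active[pop$male]) - 0.1), 3 * se1)
  expect_lt(abs(mean(log$active[!pop$male]) - 0.9), 3 * se1)

  # individuals off the transect are never detected
  off <- fixed_population(N, rep(cell_index(6, 6, N), 10), male = rep(TRUE, 10))
  log <- apply_active_capture(off, tr, cfg, new_capture_log(off))
  expect_true(!any(log$active))
})

test_that("capture sets only grow and stay within the id universe", {
  set.seed(26)
  cfg <- sim_config(grid_resolution = 8, density_multiplier = 4,
                    sampling_days = 30)
  k <- build_distance_kernel(8)
  pop <- init_population(cfg)
  layout <- build_trap_layout(cfg)
  log <- new_capture_log(pop)
  prev_p <- prev_a <- 0L
  for (day in 1:30) {
    st <- step_movement(pop, k, cfg)
    pop <- st$population
    log <- apply_passive_capture(pop, st$moved, layout, log)
    log <- apply_active_capture(pop, choose_active_transect(cfg), cfg, log)
    expect_gte(sum(log$passive), prev_p)
    expect_gte(sum(log$active), prev_a)
    prev_p <- sum(log$passive)
    prev_a <- sum(log$active)
  }
  expect_true(all(which(log$passive) %in% pop$id))
  expect_true(all(which(log$active) %in% pop$id))
})

test_that("zero sampling days yield an empty capture log", {
  set.seed(27)
  cfg <- sim_config(grid_resolution = 5, sampling_days = 0)
  pop <- init_population(cfg)
  out <- run_sampling_phase(pop, build_distance_kernel(5),
                            build_trap_layout(cfg), cfg)
  expect_equal(sum(out$log$passive), 0L)
  expect_equal(sum(out$log$active), 0L)
})

test_that("passive captures are unaffected by the detectability parameters", {
  base <- tiny_config(sampling_days = 20)
  r1 <- run_replicate(validate_config(base), 1)
  base2 <- tiny_config(sampling_days = 20, male_detectability = 0.05,
                       female_detectability = 0.95)
  r2 <- run_replicate(validate_config(base2), 1)
  expect_identical(r1[r1$method == "passive", c("male_captures", "female_captures")],
                   r2[r2$method == "passive", c("male_captures", "female_captures")])
})
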