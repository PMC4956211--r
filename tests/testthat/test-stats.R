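test_that("chi-square statistic matches the closed form on known pairs", {
  r <- chisq_gof(50, 50)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- chisq_gof(60, 40) # (10^2)/50 + (10^2)/50
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, 0.04550026, tolerance = 1e-7)
  expect_lt(r$p_value, 0.05)

  r <- chisq_gof(55, 45) # (5^2)/50 + (5^2)/50
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 0.3173105, tolerance = 1e-7)
  expect_gt(r$p_value, 0.05)
})

test_that("chi-square test agrees with the independent base-R oracle", {
  pairs <- expand.grid(m = c(0L, 1L, 2L, 7L, 50L, 499L, 5000L, 10000L),
                       f = c(0L, 1L, 3L, 12L, 50L, 501L, 5000L, 9999L))
  pairs <- pairs[pairs$m + pairs$f > 0, ]
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$m[i]; f <- pairs$f[i]
    ours <- chisq_gof(m, f)
    oracle <- suppressWarnings(stats::chisq.test(c(m, f), correct = FALSE))
    expect_lt(abs(ours$statistic - unname(oracle$statistic)), 1e-10)
    expect_lt(abs(ours$p_value - oracle$p.value), 1e-10)
  }
})

test_that("degenerate counts are rejected", {
  expect_error(chisq_gof(0, 0), "undefined")
  expect_error(chisq_gof(-1, 5), "non-negative")
})

test_that("replicates are classified by significance and direction", {
  mk_log_pop <- function(n_male_captured, n_female_captured, method) {
    n <- 400L
    pop <- fixed_population(10, rep(1L, n), male = rep(c(TRUE, FALSE), each = 200))
    flags <- logical(n)
    flags[seq_len(n_male_captured)] <- TRUE
    flags[200L + seq_len(n_female_captured)] <- TRUE
    log <- new_capture_log(pop)
    log[[method]] <- flags
    list(log = log, pop = pop)
  }

  x <- mk_log_pop(200, 200, "passive")
  res <- classify_run(x$log, x$pop, alpha = 0.05)
  expect_equal(as.character(res$classification[res$method == "passive"]),
               "unbiased")
  # the other method captured nothing: no_data, independently of the first
  expect_equal(as.character(res$classification[res$method == "active"]),
               "no_data")

  x <- mk_log_pop(90, 10, "active")
  res <- classify_run(x$log, x$pop, alpha = 0.05)
  act <- res[res$method == "active", ]
  expect_equal(act$statistic, 64) # (40^2)/50 + (40^2)/50
  expect_equal(as.character(act$classification), "male_biased")

  x <- mk_log_pop(10, 90, "active")
  res <- classify_run(x$log, x$pop, alpha = 0.05)
  expect_equal(as.character(res$classification[res$method == "active"]),
               "female_biased")

  # borderline non-significance stays unbiased
  x <- mk_log_pop(55, 45, "passive")
  res <- classify_run(x$log, x$pop, alpha = 0.05)
  expect_equal(as.character(res$classification[res$method == "passive"]),
               "unbiased")
})

test_that("aggregation counts every replicate exactly once per method", {
  set.seed(31)
  cfg <- validate_config(tiny_config(replicates = 8))
  k <- build_distance_kernel(cfg$grid_resolution)
  results <- lapply(1:8, function(i) run_replicate(cfg, i, k))
  rec <- aggregate_replicates(results, cfg)
  expect_equal(rec$MaPS + rec$FePS + rec$UnbiasedPS + rec$NoDataPS, 8L)
  expect_equal(rec$MaAS + rec$FeAS + rec$UnbiasedAS + rec$NoDataAS, 8L)
  expect_equal(rec$R, cfg$grid_resolution)
  expect_equal(rec$Days, cfg$sampling_days)
  expect_equal(rec$Mov, cfg$male_move_prob)
})

test_that("exact test size matches a Monte-Carlo estimate of the null", {
  set.seed(32)
  for (total in c(20L, 101L)) {
    m <- stats::rbinom(2e4, total, 0.5)
    p <- vapply(m, function(x) chisq_gof(x, total - x)$p_value, numeric(1))
    mc <- mean(p < 0.05)
    exact <- exact_test_size(total, 0.05)
    expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 2e4) + 1e-9)
    expect_lt(exact, 0.05 + 1e-12) # discreteness keeps the size at or below nominal
  }
  expect_equal(exact_test_size(0), 0)
})
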