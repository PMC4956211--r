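#' Chi-square goodness-of-fit test against an equal sex ratio
#'
#' Pearson goodness-of-fit of the observed unique-capture counts against the
#' expected 1:1 split: with `T = M + F`, the statistic is
#' `(M - T/2)^2 / (T/2) + (F - T/2)^2 / (T/2)` on 1 degree of freedom, with
#' no continuity correction (the conventional choice for a df = 1
#' goodness-of-fit test on a count vector).
#'
#' @param male_count,female_count Non-negative integer unique-capture counts.
#'   Their sum must be positive; a method that captured nothing has no
#'   testable sex ratio and is classified `no_data` upstream.
#' @return A list with `statistic` and `p_value`.
#' @examples
#' chisq_gof(60, 40) # statistic 4, p about 0.0455
#' @export
chisq_gof <- function(male_count, female_count) {
  total <- male_count + female_count
  if (any(c(male_count, female_count) < 0)) stop("counts must be non-negative")
  if (total == 0) stop("no captures: the sex-ratio test is undefined")
  expected <- total / 2
  statistic <- (male_count - expected)^2 / expected +
    (female_count - expected)^2 / expected
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE))
}

run_classes <- c("male_biased", "female_biased", "unbiased", "no_data")

classify_counts <- function(male_count, female_count, alpha) {
  if (male_count + female_count == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                classification = "no_data"))
  }
  ht <- chisq_gof(male_count, female_count)
  cls <- if (ht$p_value >= alpha) {
    "unbiased"
  } else if (male_count > female_count) {
    "male_biased"
  } else {
    "female_biased"
  }
  c(ht, list(classification = cls))
}

#' Classify one replicate's estimated sex ratios
#'
#' Counts the unique individuals of each sex captured by each method, tests
#' each method's counts against the true 1:1 ratio with [chisq_gof()], and
#' classifies the outcome: `male_biased` or `female_biased` when the test is
#' significant at `alpha` (direction from the count comparison), `unbiased`
#' when it is not, and `no_data` when the method captured nobody.
#'
#' @param log An `sr_capture_log` from [run_sampling_phase()].
#' @param pop The `sr_population` the log was produced on.
#' @param alpha Significance level (default from the configuration, 0.05).
#' @return An `sr_run_result`: a data frame with one row per method
#'   (`passive`, `active`) and columns `male_captures`, `female_captures`,
#'   `statistic`, `p_value`, `classification`.
#' @export
classify_run <- function(log, pop, alpha = 0.05) {
  stopifnot(inherits(log, "sr_capture_log"), inherits(pop, "sr_population"))
  one <- function(flags, method) {
    m <- sum(flags & pop$male)
    f <- sum(flags & !pop$male)
    cl <- classify_counts(m, f, alpha)
    data.frame(method = method, male_captures = m, female_captures = f,
               statistic = cl$statistic, p_value = cl$p_value,
               classification = factor(cl$classification, levels = run_classes))
  }
  res <- rbind(one(log$passive, "passive"), one(log$active, "active"))
  class(res) <- c("sr_run_result", "data.frame")
  res
}

#' Aggregate replicate classifications into one sweep-table row
#'
#' Tallies the per-replicate classifications of one parameter combination
#' into the sweep-table schema: parameter columns `R` (grid size), `Days`,
#' `SaEf` (passive effort), `Mov` (male movement probability), `DeMa`,
#' `DeFe`, and outcome columns counting replicates classified male-biased,
#' female-biased and unbiased per method (`MaPS`, `FePS`, `UnbiasedPS` for
#' passive; `MaAS`, `FeAS`, `UnbiasedAS` for active). Replicates in which a
#' method captured nothing are reported separately (`NoDataPS`, `NoDataAS`)
#' rather than inflating the unbiased tally, so per method the four columns
#' always sum to the replicate count.
#'
#' @param results List of `sr_run_result` objects from one parameter
#'   combination.
#' @param config The [sim_config()] shared by those replicates.
#' @return An `sr_sweep_record`: a one-row data frame in the schema above.
#' @export
aggregate_replicates <- function(results, config) {
  stopifnot(length(results) > 0)
  tally <- function(method) {
    cls <- vapply(results, function(r) {
      as.character(r$classification[r$method == method])
    }, character(1))
    table(factor(cls, levels = run_classes))
  }
  ps <- tally("passive")
  as <- tally("active")
  rec <- data.frame(
    R = config$grid_resolution,
    Days = config$sampling_days,
    SaEf = config$passive_effort,
    Mov = config$male_move_prob,
    DeMa = config$male_detectability,
    DeFe = config$female_detectability,
    MaPS = as.integer(ps[["male_biased"]]),
    FePS = as.integer(ps[["female_biased"]]),
    UnbiasedPS = as.integer(ps[["unbiased"]]),
    MaAS = as.integer(as[["male_biased"]]),
    FeAS = as.integer(as[["female_biased"]]),
    UnbiasedAS = as.integer(as[["unbiased"]]),
    NoDataPS = as.integer(ps[["no_data"]]),
    NoDataAS = as.integer(as[["no_data"]])
  )
  class(rec) <- c("sr_sweep_record", "data.frame")
  rec
}

#' Exact size of the chi-square sex-ratio test at a given capture total
#'
#' Because capture counts are discrete, the realised type-I error of the
#' chi-square test at level `alpha` is below nominal for small totals. Under
#' the null the male count is Binomial(`total`, 1/2); this helper sums the
#' binomial probabilities of all outcomes the test would flag as biased,
#' giving the achievable test size used to calibrate null-scenario
#' expectations.
#'
#' @param total Positive integer vector of total unique captures.
#' @param alpha Significance level.
#' @return Numeric vector of exact sizes, one per total.
#' @export
exact_test_size <- function(total, alpha = 0.05) {
  vapply(as.integer(total), function(tt) {
    if (tt == 0) return(0)
    m <- 0:tt
    stat <- (m - tt / 2)^2 / (tt / 2) + ((tt - m) - tt / 2)^2 / (tt / 2)
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    sum(stats::dbinom(m, tt, 0.5)[p < alpha])
  }, numeric(1))
}
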