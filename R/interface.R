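#' Write and read sweep tables
#'
#' Sweep tables are plain CSV with the fixed header `R, Days, SaEf, Mov,
#' DeMa, DeFe, MaPS, FePS, UnbiasedPS, MaAS, FeAS, UnbiasedAS, NoDataPS,
#' NoDataAS` — one row per parameter combination. `write_sweep_csv()` also
#' writes a YAML sidecar (`<path>.meta.yaml`) recording the base seed,
#' package version and timestamp, which together with the table's parameter
#' columns is enough to re-run any row bit-identically.
#'
#' @param records An `sr_sweep_table` (or any data frame in the schema).
#' @param path Output CSV path.
#' @return `write_sweep_csv()` returns `path` invisibly; `read_sweep_csv()`
#'   returns the table as an `sr_sweep_table`.
#' @export
write_sweep_csv <- function(records, path) {
  cols <- c("R", "Days", "SaEf", "Mov", "DeMa", "DeFe",
            "MaPS", "FePS", "UnbiasedPS", "MaAS", "FeAS", "UnbiasedAS",
            "NoDataPS", "NoDataAS")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack sweep-table column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(as.data.frame(records)[cols], path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(seed = attr(records, "seed"),
               package_version = as.character(utils::packageVersion("sexratiosim")),
               written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("sr_sweep_table", "data.frame")
  tab
}

#' Summary figure of a sweep table
#'
#' Plots, for each method, the number of replicates whose estimated sex
#' ratio was classified unbiased against the swept parameter — the standard
#' way to compare how fast each method recovers the true 1:1 ratio.
#'
#' @param records An `sr_sweep_table`.
#' @param kind Which x-axis the records vary: `"asymmetry-curves"` (male
#'   movement probability or male detectability), `"days-curves"` or
#'   `"effort-curves"`.
#' @param path Optional output file (PNG/SVG/PDF by extension); when `NULL`
#'   the ggplot object is returned without writing.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_summary <- function(records,
                         kind = c("asymmetry-curves", "days-curves",
                                  "effort-curves"),
                         path = NULL) {
  kind <- match.arg(kind)
  if (is.null(records) || nrow(records) == 0) stop("no records to plot")
  xinfo <- switch(kind,
                  "asymmetry-curves" = {
                    if (length(unique(records$Mov)) > 1) {
                      list(var = "Mov", lab = "Male movement probability")
                    } else {
                      list(var = "DeMa", lab = "Male detectability")
                    }
                  },
                  "days-curves" = list(var = "Days", lab = "Sampling days"),
                  "effort-curves" = list(var = "SaEf",
                                         lab = "Passive sampling effort"))
  if (length(unique(records[[xinfo$var]])) < 2) {
    stop("records do not vary along the requested axis (", xinfo$var, ")")
  }
  long <- rbind(
    data.frame(x = records[[xinfo$var]], unbiased = records$UnbiasedPS,
               method = "passive"),
    data.frame(x = records[[xinfo$var]], unbiased = records$UnbiasedAS,
               method = "active")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$unbiased,
                                          colour = .data$method,
                                          shape = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = c(passive = "#c23b22",
                                            active = "#2c5f9e")) +
    ggplot2::scale_shape_manual(values = c(passive = 16, active = 15)) +
    ggplot2::labs(x = xinfo$lab,
                  y = "Replicates with unbiased sex ratio",
                  colour = "Method", shape = "Method") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Built-in test fixtures
#'
#' Small fixed configurations used by the test-suite and demos: `tiny` is a
#' 5 x 5 grid with 10 sampling days and 5 replicates (sub-second end-to-end
#' runs), `small` a 10 x 10 grid with 100 sampling days and 20 replicates.
#' Both use the standard density multiplier of 4 and fixed seeds.
#'
#' @param size `"tiny"` or `"small"`.
#' @return A validated [sim_config()].
#' @examples
#' make_fixture("tiny")$n  # 100 individuals
#' make_fixture("small")$n # 400 individuals
#' @export
make_fixture <- function(size = c("tiny", "small")) {
  size <- match.arg(size)
  switch(size,
         tiny = sim_config(grid_resolution = 5L, burn_in_steps = 20L,
                           sampling_days = 10L, replicates = 5L,
                           seed = 101L),
         small = sim_config(grid_resolution = 10L, burn_in_steps = 100L,
                            sampling_days = 100L, replicates = 20L,
                            seed = 202L))
}
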