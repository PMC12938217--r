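#' Write summary tables, figures and a human-readable report
#'
#' Renders the experiment's outputs: the tidy metrics table as CSV,
#' bar charts of ignition frequency, mean duration and assembly size per
#' condition (mean over networks and assemblies, with standard-error
#' bars), and a markdown summary of the statistical results. Empty
#' metrics produce a report with explicit "no data" sections rather than
#' an error.
#'
#' @param metrics tidy metrics tibble from [compute_metrics()] rows.
#' @param stats optional list of statistical results (e.g. from
#'   [rm_anova_2x3()] and [paired_t()]).
#' @param output_dir directory to write into (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
report <- function(metrics, stats = NULL, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)
  }
  files <- character()
  md <- c("# Simulation report", "")

  if (is.null(metrics) || nrow(metrics) == 0) {
    md <- c(md, "## Metrics", "", "no data", "")
  } else {
    f <- file.path(output_dir, "metrics.csv")
    write.csv(metrics, f, row.names = FALSE)
    files <- c(files, f)
    se <- function(x) sd(x) / sqrt(length(x))
    summ <- metrics |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        frequency_mean = mean(.data$frequency), frequency_se = se(.data$frequency),
        duration_mean = mean(.data$mean_duration, na.rm = TRUE),
        duration_se = se(.data$mean_duration[!is.na(.data$mean_duration)]),
        size_mean = mean(.data$size), size_se = se(.data$size), .groups = "drop")
    f <- file.path(output_dir, "condition_summary.csv")
    write.csv(summ, f, row.names = FALSE)
    files <- c(files, f)
    for (what in c("frequency", "duration", "size")) {
      p <- ggplot2::ggplot(summ, ggplot2::aes(
        x = .data$condition,
        y = .data[[paste0(what, "_mean")]])) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data[[paste0(what, "_mean")]] - .data[[paste0(what, "_se")]],
          ymax = .data[[paste0(what, "_mean")]] + .data[[paste0(what, "_se")]]),
          width = 0.25) +
        ggplot2::labs(x = NULL, y = paste("mean", what)) +
        ggplot2::theme_minimal()
      f <- file.path(output_dir, paste0(what, "_by_condition.pdf"))
      ggplot2::ggsave(f, p, width = 5, height = 4)
      files <- c(files, f)
    }
    md <- c(md, "## Condition summary", "",
            paste(utils::capture.output(print(as.data.frame(summ))), collapse = "\n"), "")
  }

  if (is.null(stats) || length(stats) == 0) {
    md <- c(md, "## Statistics", "", "no data", "")
  } else {
    md <- c(md, "## Statistics", "")
    for (nm in names(stats)) {
      md <- c(md, paste0("### ", nm), "",
              paste(utils::capture.output(print(stats[[nm]])), collapse = "\n"), "")
    }
  }
  f <- file.path(output_dir, "report.md")
  writeLines(md, f)
  files <- c(files, f)
  invisible(files)
}
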