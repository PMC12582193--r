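# Reporting: deterministic CSV tables and the standard figure panels
# (threshold-by-response traces, bCFS/reCFS dot plots, depth bars with
# within-participant error bars). Every figure's data table is written
# alongside the image so the plotted numbers are inspectable.

#' Write analysis results and figures to a directory
#'
#' @param log the tidy trial log the analysis was run on (used for the
#'   threshold-by-response trace panel).
#' @param results output of [analyze_tcfs()].
#' @param out_dir output directory (created if needed).
#' @param figures write PDF figures as well as CSV tables.
#' @return invisibly, a character vector of the files written.
#' @export
report_tcfs <- function(log, results, out_dir, figures = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    written <<- c(written, path)
  }
  wr(results$summaries, "summaries.csv")
  wr(results$screening, "screening.csv")
  wr(results$anova_thresholds, "anova_thresholds.csv")
  wr(results$anova_depth, "anova_depth.csv")
  wr(results$posthoc_depth, "posthoc_depth.csv")
  wr(results$condition_means, "condition_means.csv")

  # trace panel data: mean contrast per response index per condition, with
  # the 0 dB trial start prepended as response 0
  trace_df <- log |>
    dplyr::group_by(.data$condition, .data$response_index, .data$kind) |>
    dplyr::summarise(mean_db = mean(.data$contrast_db), .groups = "drop")
  start_df <- tibble::tibble(
    condition = unique(log$condition), response_index = 0L,
    kind = "start", mean_db = 0
  )
  trace_df <- dplyr::bind_rows(start_df, trace_df) |>
    dplyr::arrange(.data$condition, .data$response_index)
  wr(trace_df, "trace_panel.csv")

  depth_df <- dplyr::left_join(
    results$sem_depth,
    dplyr::select(results$condition_means, "condition", "mean_depth_db"),
    by = "condition"
  )
  wr(depth_df, "depth_panel.csv")

  if (figures) {
    p_trace <- ggplot2::ggplot(trace_df,
        ggplot2::aes(x = .data$response_index, y = .data$mean_db,
                     colour = .data$condition)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(ggplot2::aes(shape = .data$kind)) +
      ggplot2::labs(x = "Response index", y = "Contrast (dB)",
                    title = "Mean threshold per response") +
      ggplot2::theme_minimal()
    f1 <- file.path(out_dir, "trace_panel.pdf")
    ggplot2::ggsave(f1, p_trace, width = 7, height = 4)

    long <- thresholds_long(results$summaries)
    p_thresh <- ggplot2::ggplot(long,
        ggplot2::aes(x = .data$condition, y = .data$value,
                     colour = .data$kind, group = interaction(.data$participant, .data$kind))) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_line(alpha = 0.2, colour = "grey50") +
      ggplot2::labs(x = NULL, y = "Threshold (dB)",
                    title = "bCFS and reCFS thresholds") +
      ggplot2::theme_minimal()
    f2 <- file.path(out_dir, "thresholds_panel.pdf")
    ggplot2::ggsave(f2, p_thresh, width = 7, height = 4)

    p_depth <- ggplot2::ggplot(depth_df,
        ggplot2::aes(x = .data$condition, y = .data$mean)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem_ws,
                                          ymax = .data$mean + .data$sem_ws),
                             width = 0.2) +
      ggplot2::geom_point(data = results$summaries,
                          ggplot2::aes(y = .data$depth_db), alpha = 0.4) +
      ggplot2::labs(x = NULL, y = "Suppression depth (dB)",
                    title = "Suppression depth (bCFS - reCFS), +/- 1 within-participant SEM") +
      ggplot2::theme_minimal()
    f3 <- file.path(out_dir, "depth_panel.pdf")
    ggplot2::ggsave(f3, p_depth, width = 7, height = 4)
    written <- c(written, f1, f2, f3)
  }
  invisible(written)
}
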