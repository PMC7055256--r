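# Trajectory plots mirroring the QTN-by-dominance panel grids.

#' Plot aggregated trajectories
#'
#' Mean +/- SD ribbons of a chosen statistic over cycles, one line per
#' strategy, facetted by QTN level and mean dominance degree. Requires
#' ggplot2.
#'
#' @param summary output of [aggregate_replicates()] (or the `summary`
#'   element of [run_grid()]).
#' @param stat statistic to plot: `"hybrid_mean"`, `"inbred_mean"`,
#'   `"hybrid_var"`, `"inbred_var"`, `"pc1_mean"`, ...
#' @return A ggplot object.
#' @export
plot_trajectories <- function(summary, stat = "hybrid_mean") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    fail("plot_trajectories() requires the ggplot2 package")
  mcol <- paste0(stat, "_mean")
  scol <- paste0(stat, "_sd")
  if (!mcol %in% names(summary))
    fail("statistic '%s' not found in the summary", stat)
  df <- summary
  if ("pool" %in% names(df) && !startsWith(stat, "pc1"))
    df <- df[!duplicated(df[intersect(c("strategy", "n_qtn", "dom_mean",
                                        "cycle"), names(df))]), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cycle, y = .data[[mcol]],
    colour = .data$strategy, fill = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                      ymax = .data[[mcol]] + .data[[scol]]),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle", y = stat) +
    ggplot2::theme_minimal()
  if (all(c("n_qtn", "dom_mean") %in% names(df)))
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$dom_mean),
      cols = ggplot2::vars(.data$n_qtn), labeller = ggplot2::label_both)
  p
}
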