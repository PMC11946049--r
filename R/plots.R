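# Waterfall and change-distribution figures.

#' Waterfall plot of per-lesion maximum changes
#'
#' One bar per lesion (sorted descending) showing the maximal-magnitude
#' percent change in diameter, faceted by phase, with the +20% progression
#' and -30% response thresholds drawn as dashed lines.
#'
#' @param report a `cect_report` from [analyze_study()].
#' @param thresholds a [criteria_thresholds()] for the reference lines.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(report, thresholds = criteria_thresholds()) {
  stopifnot(inherits(report, "cect_report"))
  wf <- report$diameter$waterfall_by_phase
  wf <- do.call(rbind, lapply(split(wf, wf$phase), function(w) {
    w <- w[order(-w$max_percent_change), ]
    w$rank <- seq_len(nrow(w))
    w
  }))
  ggplot2::ggplot(wf, ggplot2::aes(x = rank, y = max_percent_change)) +
    ggplot2::geom_col(width = 0.85, fill = "grey35") +
    ggplot2::geom_hline(yintercept = thresholds$pd_diameter_increase,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = thresholds$pr_diameter_decrease,
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "Lesion (sorted)",
                  y = "Maximum % change in diameter from baseline") +
    ggplot2::theme_minimal()
}

#' Histogram of paired percent differences
#'
#' Distribution of all paired diameter changes, with the +/-10% band that
#' repeat measurements typically fall within.
#'
#' @param report a `cect_report`.
#' @param binwidth histogram bin width in percent.
#' @return A ggplot object.
#' @export
plot_change_histogram <- function(report, binwidth = 1) {
  stopifnot(inherits(report, "cect_report"))
  ch <- report$diameter$changes
  ggplot2::ggplot(ch, ggplot2::aes(x = percent_difference)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = c(-10, 10), linetype = "dashed") +
    ggplot2::labs(x = "% difference from baseline", y = "Pairs") +
    ggplot2::theme_minimal()
}

save_plot <- function(p, path, width = 7, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
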