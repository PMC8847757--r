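#' Plot helpers
#'
#' Quick ggplot2 views of the package's standard outputs: a
#' resource-by-efficiency heatmap of the proportion of cooperators
#' (`plot_coop_heatmap`), cell summaries with cross-replicate error bars
#' (`plot_sweep_summary`), replicate-averaged time series with a mean-sd
#' ribbon (`plot_aggregate`), a lag-correlation curve (`plot_tlcc`) and an
#' amplitude spectrum (`plot_spectrum`).
#'
#' @param summary A `sweep_summary` from [run_sweep()] (needs `R00` and
#'   `bK` columns for the heatmap).
#' @param y Summary column to plot (e.g. `"mean_prop_coop"`, `"mean_N"`).
#' @return A ggplot object.
#' @name coopdyn-plots
NULL

#' @rdname coopdyn-plots
#' @export
plot_coop_heatmap <- function(summary) {
  stopifnot(all(c("R00", "bK") %in% names(summary)))
  ggplot2::ggplot(summary,
                  ggplot2::aes(factor(R00), factor(bK),
                               fill = mean_prop_coop)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "environmental resource availability (R00)",
                  y = "cooperation efficiency (bK)",
                  fill = "prop.\ncooperators") +
    ggplot2::theme_minimal()
}

#' @rdname coopdyn-plots
#' @export
plot_sweep_summary <- function(summary, y = "mean_prop_coop") {
  sdcol <- sub("^mean_", "sd_", y)
  df <- as.data.frame(summary)
  df$y <- df[[y]]
  df$ymin <- df$y - df[[sdcol]]
  df$ymax <- df$y + df[[sdcol]]
  grp <- if ("bK" %in% names(df)) factor(df$bK) else factor(df$scenario)
  df$grp <- grp
  p <- ggplot2::ggplot(df, ggplot2::aes(R00, y, colour = grp, group = grp)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ymin, ymax = ymax),
                           width = 0.15) +
    ggplot2::labs(x = "environmental resource availability (R00)", y = y,
                  colour = if ("bK" %in% names(df)) "bK" else "scenario") +
    ggplot2::theme_minimal()
  if ("scenario" %in% names(df) && "bK" %in% names(df) &&
      length(unique(df$scenario)) > 1)
    p <- p + ggplot2::facet_wrap(~scenario)
  p
}

#' @rdname coopdyn-plots
#' @param agg An `aggregate_series` from [aggregate_replicates()].
#' @param var Observable to plot (e.g. `"N"`, `"prop_coop"`).
#' @export
plot_aggregate <- function(agg, var = "N") {
  m <- agg[[paste0("mean_", var)]]
  s <- agg[[paste0("sd_", var)]]
  df <- data.frame(t = agg$t, m = m,
                   lo = m - s, hi = m + s)
  ggplot2::ggplot(df, ggplot2::aes(t, m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = var) +
    ggplot2::theme_minimal()
}

#' @rdname coopdyn-plots
#' @param lc A `lag_correlation` from [tlcc()] or
#'   [fluctuation_synchrony()].
#' @export
plot_tlcc <- function(lc) {
  ggplot2::ggplot(as.data.frame(lc), ggplot2::aes(lag, r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (steps)", y = "cross-correlation") +
    ggplot2::theme_minimal()
}

#' @rdname coopdyn-plots
#' @param sp A `pop_spectrum` from [population_spectrum()] or
#'   [fluctuation_spectrum()].
#' @export
plot_spectrum <- function(sp) {
  ggplot2::ggplot(as.data.frame(sp), ggplot2::aes(freq, amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (cycles per step)",
                  y = "amplitude of (N - mean)/mean") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("mean_prop_coop", "R00", "y", "ymin", "ymax",
                         "grp", "m", "lo", "hi", "lag", "r", "freq",
                         "amplitude"))
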