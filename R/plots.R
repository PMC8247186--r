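# ggplot2 views of the main result types.

#' Plot a windowed copy-number profile
#'
#' Points are per-window copy numbers; the step line shows segment means when
#' segmentation has been run. Masked (gap) windows are omitted.
#'
#' @param profile CNV profile tibble (or a `cbs_fit`).
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(profile) {
  if (inherits(profile, "cbs_fit")) profile <- profile$profile
  df <- profile[!profile$gap, , drop = FALSE]
  df$mb <- (df$start + df$end) / 2e6
  p <- ggplot(df, aes(x = .data$mb, y = .data$copy_number)) +
    geom_point(size = 0.6, alpha = 0.6) +
    facet_grid(cols = vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "position (Mb)", y = "copy number") +
    theme_bw()
  if ("segment_mean" %in% names(df) && any(!is.na(df$segment_mean))) {
    p <- p + geom_step(aes(y = .data$segment_mean), colour = "red",
                       linewidth = 0.7)
  }
  p
}

#' @rdname plot_cnv_profile
#' @param object A `cbs_fit` object.
#' @param ... Unused.
#' @export
autoplot.cbs_fit <- function(object, ...) plot_cnv_profile(object)

#' @rdname mutation_spectrum
#' @param object A `mutation_spectrum` tibble.
#' @param ... Unused.
#' @export
autoplot.mutation_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$class, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    labs(x = "substitution class", y = "fraction of SNVs") +
    theme_bw()
}

#' Plot precision/recall against the multi-cell support threshold
#'
#' @param trend Tibble with a support-threshold column (`min_cells` or `k`)
#'   and metric columns `precision` and `recall` (e.g. a row-bound set of
#'   [compute_metrics()] results or [snv_multicell_support()] output).
#' @return A ggplot object.
#' @export
plot_support_trend <- function(trend) {
  xcol <- intersect(c("min_cells", "k"), names(trend))[1]
  if (is.na(xcol)) abort("trend needs a min_cells or k column")
  keep <- intersect(c("precision", "recall", "efficiency", "fpr", "fnr"),
                    names(trend))
  long <- pivot_longer(trend[, c(xcol, keep)], all_of(keep),
                       names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data[[xcol]], y = .data$value,
                   colour = .data$metric)) +
    geom_line() + geom_point() +
    labs(x = "minimum supporting cells", y = "metric value") +
    theme_bw()
}
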