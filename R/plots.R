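#' Plot phantom compartment fraction maps
#'
#' @param object An `asl_phantom`.
#' @param ... Unused.
#' @return A ggplot faceting the CSF and tissue partial-volume fractions.
#' @export
autoplot.asl_phantom <- function(object, ...) {
  g <- object$spec$grid
  d <- tidyr::expand_grid(row = seq_len(g), col = seq_len(g))
  d$CSF <- as.vector(object$frac_csf)
  d$tissue <- as.vector(object$frac_tissue)
  long <- tidyr::pivot_longer(d, c("CSF", "tissue"),
                              names_to = "compartment", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot ROI difference-signal time courses of an ASL series
#'
#' @param series An [asl_series()].
#' @param roi An [roi_spec()].
#' @param aggregate Passed to [roi_series()].
#' @return A ggplot of control and difference signal against TI.
#' @export
plot_roi_timecourse <- function(series, roi, aggregate = "sum") {
  d <- roi_series(series, roi, aggregate = aggregate)
  long <- tidyr::pivot_longer(d, c("control", "dm"),
                              names_to = "signal_type", values_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ti, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal_type, scales = "free_y") +
    ggplot2::labs(x = "inversion time (s)", y = "ROI signal") +
    ggplot2::theme_minimal()
}

#' Group comparison dot plot for a quantified cohort
#'
#' @param data Data frame with a value column and a group column (e.g. the
#'   output of [quantify_cohort()] for two groups bound together).
#' @param value,group Column names (strings).
#' @return A ggplot of individual values with group means.
#' @export
plot_cohort <- function(data, value = "f_bcsfb", group = "group") {
  stopifnot(value %in% names(data), group %in% names(data))
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]], y = .data[[value]])) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "steelblue") +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}
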