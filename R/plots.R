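#' @export
autoplot.threshold_scan <- function(object, plateau = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mc), colour = "grey60",
                        size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "MitoTracker intensity threshold (a.u.)",
                  y = "medcouple of retained growth rates")
  if (!is.null(object$mc_smooth)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$mc_smooth),
                                na.rm = TRUE)
  }
  if (!is.null(plateau)) {
    p <- p + ggplot2::annotate("rect", xmin = plateau$lo, xmax = plateau$hi,
                               ymin = -Inf, ymax = Inf, alpha = 0.2,
                               fill = "red")
  }
  p
}

#' Growth-rate cumulative density curves before/after petite exclusion
#'
#' The vertical axis uses a square-root scale, which magnifies the
#' slower-growing tails where the populations differ.
#'
#' @param before,after Numeric growth-rate vectors.
#' @return A ggplot object.
#' @export
plot_growth_cdf <- function(before, after) {
  df <- dplyr::bind_rows(
    tibble(set = "before", rate = sort(before),
           cdf = seq_along(before) / length(before)),
    tibble(set = "after", rate = sort(after),
           cdf = seq_along(after) / length(after))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$cdf,
                                   linetype = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "growth rate (1/h)", y = "cumulative density (sqrt scale)")
}
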