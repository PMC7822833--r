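#' Plot a Moran's I correlogram
#'
#' Moran's I against distance-class midpoint, with significant classes
#' (permutation p below `alpha`) filled and the no-autocorrelation
#' expectation `-1/(n-1)` as a dashed line.
#'
#' @param object A [correlogram()].
#' @param alpha Significance level for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlogram
#' @export
autoplot.correlogram <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$empty)
  df$mid_km <- (df$lower_km + df$upper_km) / 2
  df$significant <- df$p_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_km, y = .data$morans_i)) +
    ggplot2::geom_hline(yintercept = attr(object, "expectation"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white"),
                               name = paste0("p < ", alpha)) +
    ggplot2::labs(x = "Distance class midpoint (km)", y = "Moran's I") +
    ggplot2::theme_minimal()
}

#' Plot per-term relative importance
#'
#' Horizontal bars of RI (%) per fixed term, with the selection threshold
#' as a dashed line.
#'
#' @param object An [relative_importance()] table.
#' @param threshold RI threshold to display (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ri_table
#' @export
autoplot.ri_table <- function(object, threshold = 50, ...) {
  df <- tibble::as_tibble(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ri, y = .data$term)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Relative importance (%)", y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot per-group covariate slopes
#'
#' Point estimates with 95% confidence bars for each group's slope, with
#' zero marked; groups whose interval crosses zero are drawn transparent.
#'
#' @param object An [extract_group_slopes()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_slopes
#' @export
autoplot.group_slopes <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p.value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope, y = .data$level,
                                   alpha = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "Slope (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
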