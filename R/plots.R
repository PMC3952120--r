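#' Scatter plot of calculated versus experimental binding energies
#'
#' Draws the paired observations with the fitted least-squares line and the
#' identity line, the standard way this class of predictor is reported.
#'
#' @param data A data frame of paired observations.
#' @param x,y Columns (tidy-eval) holding the experimental and predicted
#'   values; default `x` and `y`.
#' @param through_origin Force the displayed fit through the origin.
#' @return A ggplot object.
#' @export
plot_affinity_fit <- function(data, x = x, y = y, through_origin = FALSE) {
  v <- eval_pair(data, enquo(x), enquo(y))
  df <- tibble(x = v$x, y = v$y)
  line <- fit_regression(df, through_origin = through_origin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = line["slope"],
                         intercept = line["intercept"], colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "experimental ΔG (kcal/mol)",
                  y = "calculated ΔG (kcal/mol)",
                  subtitle = sprintf("y = %.2fx %+.2f", line["slope"],
                                     line["intercept"])) +
    ggplot2::theme_minimal()
}

#' @rdname plot_affinity_fit
#' @param object An `fb_potential`.
#' @param ... Unused.
#' @method autoplot fb_potential
#' @export
autoplot.fb_potential <- function(object, ...) {
  df <- tidy(object) %>% filter(!is.na(.data$s))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$quad, .data$s),
                                   y = .data$s)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "atomic quadruplet",
                  y = expression(s == log[10](f / p))) +
    ggplot2::theme_minimal(base_size = 7)
}
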