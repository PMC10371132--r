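# ggplot2 methods for the package's result types.

#' Plot a production envelope
#'
#' Feasible product-flux band (shaded) against growth, with the lower
#' (guaranteed) and upper edges drawn as lines.
#'
#' @param object a [production_envelope()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.production_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$growth)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$product_min, ymax = .data$product_max),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$product_max), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$product_min), color = "steelblue4") +
    ggplot2::labs(
      x = expression(paste("growth rate (", h^-1, ")")),
      y = expression(paste("product flux (mmol ", gDW^-1, h^-1, ")")),
      title = paste0("Production envelope: ", attr(object, "product"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enumeration result
#'
#' Number of minimal qualifying strategies per knockout cardinality, split
#' by qualification mode.
#'
#' @param object a `knockout_enumeration`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.knockout_enumeration <- function(object, ...) {
  counts <- object$records |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      rate_max = sum(.data$minimal_max),
      rate_grnt = sum(.data$minimal_grnt),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("rate_max", "rate_grnt"),
                        names_to = "mode", values_to = "n")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = factor(.data$level), y = .data$n,
                               fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "knockout cardinality", y = "minimal solutions",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot knockout strategies in the growth-production plane
#'
#' One point per strategy at (growth, guaranteed production rate), sized by
#' the best-case rate.
#'
#' @param sol a solutions tibble from [solutions()].
#' @return a ggplot object.
#' @export
plot_solution_map <- function(sol) {
  ggplot2::ggplot(sol, ggplot2::aes(x = .data$growth, y = .data$product_min,
                                    size = .data$product_max)) +
    ggplot2::geom_point(alpha = 0.6, color = "firebrick") +
    ggplot2::labs(
      x = expression(paste("growth rate (", h^-1, ")")),
      y = expression(paste("guaranteed product flux (mmol ", gDW^-1, h^-1, ")")),
      size = "max rate"
    ) +
    ggplot2::theme_minimal()
}
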