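# ggplot2 helpers for the two result types users plot: per-triad ternary
# positions and category-shift matrices.

triangle_outline <- function() {
  tibble(
    x = c(0, 1, 0.5, 0),
    y = c(0, 0, sqrt(3) / 2, 0)
  )
}

#' Ternary plot of triad relative abundances
#'
#' Draws each expressed triad at its ternary coordinates inside the
#' unit-edge triangle (corners A bottom-left, B bottom-right, D top),
#' coloured by bias category, optionally faceted by condition.
#'
#' @param bias A [triad_bias()] tibble.
#' @param facet_by_condition Facet panels per condition (default `TRUE` when
#'   more than one condition is present).
#' @return A ggplot object.
#' @export
plot_ternary <- function(bias, facet_by_condition = NULL) {
  pts <- filter(bias, .data$expressed)
  facet_by_condition <- facet_by_condition %||%
    (length(unique(pts$condition)) > 1L)
  corners <- tibble(
    x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2),
    label = c("A", "B", "D"),
    vjust = c(1.6, 1.6, -0.8)
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = triangle_outline(), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                        alpha = 0.8, size = 1.6) +
    ggplot2::geom_text(
      data = corners,
      ggplot2::aes(label = .data$label, vjust = .data$vjust),
      size = 4
    ) +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::labs(colour = "Category") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
  if (facet_by_condition) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}

#' @rdname plot_ternary
#' @param object A [shift_table()] result (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.bias_shift <- function(object, ...) {
  long <- tidy.bias_shift(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$to, levels = BIAS_CATEGORIES),
    y = factor(.data$from, levels = rev(BIAS_CATEGORIES)),
    fill = .data$n
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue") +
    ggplot2::labs(
      x = paste0("Category (", object$conditions[2], ")"),
      y = paste0("Category (", object$conditions[1], ")"),
      fill = "Triads"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
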