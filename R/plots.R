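# ggplot2 views of the main result types.

#' Plot a rejection-frequency matrix
#'
#' Heatmap of rejection frequency over the gain x loss grid, with the 50%
#' accept/reject boundary drawn as a contour.
#'
#' @param cells Output of [rejection_matrix()].
#' @return A ggplot object.
#' @export
plot_rejection_matrix <- function(cells) {
  gain_col <- intersect(c("gain_pct", "usd_gain"), names(cells))[1]
  loss_col <- intersect(c("loss_pct", "usd_loss"), names(cells))[1]
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data[[gain_col]], y = .data[[loss_col]], fill = .data$rejection_rate
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_contour(
      ggplot2::aes(z = .data$rejection_rate),
      breaks = 0.5, colour = "grey40", linewidth = 0.6
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = 0.5, limits = c(0, 1), name = "P(reject)"
    ) +
    ggplot2::labs(x = paste0("gain level (", gain_col, ")"),
                  y = paste0("loss level (", loss_col, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a model's subjective value function
#'
#' The valuation curve over the signed condition axis (effort change in
#' N·s/m relative to the 35 N·s/m reference, or dollars), with the identity
#' line for comparison.
#'
#' @param model A [choice_model()].
#' @param params Named free-parameter values.
#' @return A ggplot object.
#' @export
plot_value_function <- function(model, params) {
  sv <- sv_by_condition(model, params) %>%
    mutate(signed = ifelse(.data$domain == "gain", .data$condition, -.data$condition))
  ggplot2::ggplot(sv, ggplot2::aes(x = .data$signed, y = .data$sv)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(
      x = if (model$domain == "effort") {
        "effort change relative to reference (gain > 0), N·s/m"
      } else {
        "dollar outcome (gain > 0)"
      },
      y = "subjective value"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bms_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$model, -.data$pxp), y = .data$pxp
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 1 / nrow(dat), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "protected exceedance probability",
                  subtitle = sprintf("Bayesian omnibus risk = %.3g", object$bor)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.confusion_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$selected, y = .data$generating, fill = .data$n_wins
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_wins)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac", name = "wins") +
    ggplot2::labs(x = "selected model", y = "generating model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
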