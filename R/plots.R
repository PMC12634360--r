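#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot Lasso coefficient trajectories
#'
#' Coefficient paths against the penalty (log scale, decreasing to the
#' right, so features "switch on" left to right in activation order).
#'
#' @param object A `ddss_lasso_path`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddss_lasso_path <- function(object, ...) {
  df <- tidy(object)
  df$log_lambda <- log10(df$lambda)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_lambda,
                                   y = .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(log[10](lambda) ~ "(decreasing)"),
                  y = "standardized coefficient", colour = "indicator",
                  title = "Lasso regularization trajectories") +
    ggplot2::theme_minimal()
}

#' Plot a monthly learning curve
#'
#' Heatmap of coefficient magnitude at the truncation penalty per
#' indicator and month; retained factors (|coefficient| >= tau) are
#' outlined. Months conventionally inspected in the workflow (1, 5, 8, 10)
#' can be highlighted.
#'
#' @param object A `ddss_learning_curve`.
#' @param tau Retention threshold used for the outline (default 0.05).
#' @param highlight Months to mark with a dashed line
#'   (default `c(1, 5, 8, 10)`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddss_learning_curve <- function(object, tau = 0.05,
                                         highlight = c(1, 5, 8, 10), ...) {
  df <- object |>
    dplyr::filter(!purrr::map_lgl(.data$coefs, is.null)) |>
    dplyr::mutate(coefs = purrr::map(.data$coefs, ~ tibble::tibble(
      indicator = names(.x), coefficient = unname(.x)))) |>
    dplyr::select("month", "coefs") |>
    tidyr::unnest("coefs")
  highlight <- intersect(highlight, object$month)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$indicator)) +
    ggplot2::geom_tile(ggplot2::aes(fill = abs(.data$coefficient))) +
    ggplot2::geom_point(data = dplyr::filter(df,
                                             abs(.data$coefficient) >= tau),
                        shape = 21, size = 2, colour = "white") +
    ggplot2::geom_vline(xintercept = highlight, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_viridis_c(name = "|coefficient|") +
    ggplot2::scale_x_continuous(breaks = object$month) +
    ggplot2::labs(x = "month since joining", y = NULL,
                  title = "Retained difficulty factors by month") +
    ggplot2::theme_minimal()
}

#' Plot a decoupling partition
#'
#' Heatmap of the pairwise Levenshtein distance matrix with surgeons
#' ordered by cluster, annotated with cluster membership.
#'
#' @param object A `ddss_partition` carrying a `distances` attribute
#'   (as returned by [decouple_surgeons()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddss_partition <- function(object, ...) {
  D <- attr(object, "distances")
  if (is.null(D)) stop("partition carries no distance matrix")
  ord <- object$surgeon_id[order(object$cluster, object$surgeon_id)]
  df <- tidyr::expand_grid(a = ord, b = ord) |>
    dplyr::mutate(distance = purrr::map2_dbl(.data$a, .data$b,
                                             ~ D[.x, .y]),
                  a = factor(.data$a, levels = ord),
                  b = factor(.data$b, levels = rev(ord)))
  lab <- paste0(object$surgeon_id, " (", object$cluster, ")")
  names(lab) <- object$surgeon_id
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::scale_x_discrete(labels = lab) +
    ggplot2::scale_y_discrete(labels = lab) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Preference-sequence distances by cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a confusion matrix
#'
#' @param object A `ddss_metrics` object.
#' @param ... Unused.
#' @return A ggplot of the 3x3 confusion matrix.
#' @export
autoplot.ddss_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("Accuracy %.3f, macro-AUC %.3f",
                                  object$accuracy, object$macro_auc)) +
    ggplot2::theme_minimal()
}
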