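# ggplot2 displays for fitted protocols and fragment enrichment.

#' Observed-versus-predicted scatter plot
#'
#' @param data Tibble with columns `observed` and `predicted` (e.g. the
#'   `validation` element of a `qsar_protocol`).
#' @param title Optional plot title.
#' @return A ggplot object: scatter with the identity line and the
#'   Pearson R annotated.
#' @export
plot_observed_predicted <- function(data, title = NULL) {
  r <- if (nrow(data) >= 3 && sd(data$observed) > 0 &&
           sd(data$predicted) > 0)
    cor(data$observed, data$predicted) else NA_real_
  ggplot2::ggplot(data, ggplot2::aes(x = .data$observed,
                                     y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Observed pIC50", y = "Predicted pIC50", title = title,
      subtitle = if (!is.na(r)) sprintf("Pearson R = %.3f", r) else NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qsar_protocol <- function(object, ...) {
  plot_observed_predicted(
    object$validation,
    title = sprintf("%s protocol: validation set", object$protocol))
}

#' Plot fragment class-frequency enrichment
#'
#' Bar chart of the most class-enriched fragments from a
#' [fragment_frequency_table()] result.
#'
#' @param freq_table Output of [fragment_frequency_table()].
#' @param top_n Number of fragments shown (ranked by the spread of
#'   frequency across classes).
#' @return A ggplot object.
#' @export
plot_fragment_enrichment <- function(freq_table, top_n = 20) {
  spread <- freq_table |>
    group_by(.data$fragment_id) |>
    summarise(spread = max(.data$frequency) - min(.data$frequency),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$spread)) |>
    head(top_n)
  ggplot2::ggplot(
    freq_table |> filter(.data$fragment_id %in% spread$fragment_id),
    ggplot2::aes(x = stats::reorder(.data$fragment_id, .data$frequency),
                 y = .data$frequency, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Class frequency / overall frequency",
                  fill = "Class") +
    ggplot2::theme_minimal()
}
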