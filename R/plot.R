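#' Heatmap of a confusion matrix
#'
#' Tile heatmap of an evaluator's confusion matrix (rows = predicted,
#' columns = reference, canonical category order), shaded by row-wise
#' proportion and labelled with counts.
#'
#' @param object An `"abg_confusion"` from [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abg_confusion
#' @export
autoplot.abg_confusion <- function(object, ...) {
  df <- tidy(object)
  lev <- abg_categories()
  df$predicted <- factor(df$predicted, levels = rev(lev))
  df$reference <- factor(df$reference, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$predicted,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0,
                                                   .data$count, "")),
                       size = 3.3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "white", limits = c(0, 1),
                                 name = "Row\nproportion") +
    ggplot2::labs(title = paste("Confusion matrix:", object$evaluator),
                  x = "Reference category", y = "Predicted category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-case harm score distributions
#'
#' Jittered per-case harm scores with the evaluator means, the visual
#' counterpart of the harm-weighted comparison.
#'
#' @param object An `"abg_harm_summary"` from
#'   [bootstrap_harm_difference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abg_harm_summary
#' @export
autoplot.abg_harm_summary <- function(object, ...) {
  df <- tidy(object)
  means <- dplyr::summarise(dplyr::group_by(df, .data$evaluator),
                            harm = mean(.data$harm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$evaluator, y = .data$harm)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.45,
                         color = "grey40") +
    ggplot2::geom_point(data = means, shape = 18, size = 4,
                        color = "firebrick") +
    ggplot2::labs(title = "Harm-weighted misclassification scores",
                  subtitle = sprintf("mean difference %s - %s = %.3f (%.0f%% CI %.3f to %.3f)",
                                     object$evaluator_b, object$evaluator_a,
                                     object$delta, 100 * object$conf_level,
                                     object$ci_low, object$ci_high),
                  x = NULL, y = "Per-case harm score") +
    ggplot2::theme_minimal()
}

#' Bar chart of detection metrics with exact intervals
#'
#' Plots any tibble of detection metrics (as returned by
#' [mixed_detection()], [component_detection()], ...) as bars with
#' Clopper-Pearson error bars, faceted by metric when several evaluators
#' are combined.
#'
#' @param metrics A detection-metrics tibble (columns `evaluator`,
#'   `metric`, `estimate`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_detection <- function(metrics) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$evaluator,
                                        y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportion (exact 95% CI)") +
    ggplot2::theme_minimal()
}
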