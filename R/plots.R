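# ggplot2 views of the result objects.

#' Plot estimated vs true MMSE scores
#'
#' Scatter of cross-validated score estimates against the true scores, with
#' the classification threshold drawn on both axes; points are coloured by
#' classification outcome.
#'
#' @param object A `dualgait_estimation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dualgait_estimation <- function(object, ...) {
  d <- object$predictions %>%
    mutate(outcome = ifelse(.data$true_class == .data$predicted_class,
                            "correct", "misclassified"))
  ggplot2::ggplot(d, ggplot2::aes(.data$mmse, .data$predicted_mmse,
                                  colour = .data$outcome)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "true MMSE", y = "estimated MMSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot feature importances
#'
#' @param object A `dualgait_importance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dualgait_importance <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(feature = stats::reorder(.data$feature, .data$importance))
  ggplot2::ggplot(d, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "coefficient of determination", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot first-trial vs experienced contrasts
#'
#' Group means per MMSE stratum and measure, with Bonferroni-adjusted
#' significance annotated (`*` p < 0.05, `**` p < 0.001).
#'
#' @param object A `dualgait_contrast` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dualgait_contrast <- function(object, ...) {
  d <- as_tibble(object) %>%
    tidyr::pivot_longer(c("first_mean", "experienced_mean"),
                        names_to = "when", values_to = "mean") %>%
    mutate(when = ifelse(.data$when == "first_mean", "first trial",
                         "after 41st"),
           label = dplyr::case_when(.data$sig_001 ~ "**",
                                    .data$sig_05 ~ "*",
                                    TRUE ~ ""))
  ggplot2::ggplot(d, ggplot2::aes(.data$stratum, .data$mean,
                                  fill = .data$when)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       position = ggplot2::position_dodge(0.9),
                       vjust = -0.3, size = 5) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "MMSE stratum", y = "group mean", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
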