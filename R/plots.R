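# ggplot2 visualisations for the main result types.

#' Plot an empirical ROC curve
#'
#' @inheritParams roc_auc
#' @param specificity_floor If non-`NULL`, shade the pAUC window
#'   (false-positive rate below `1 - specificity_floor`).
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels, specificity_floor = 0.95) {
  pts <- roc_points(scores, labels)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "Sensitivity",
                  title = sprintf("AUC = %.3f", roc_auc(scores, labels))) +
    ggplot2::theme_minimal()
  if (!is.null(specificity_floor)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = 1 - specificity_floor,
                               ymin = 0, ymax = 1, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' @describeIn screen_transcripts AUC vs pAUC scatter of all transcripts,
#'   coloured by candidate selection.
#' @param object A `screen_result`.
#' @param ... Unused.
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$pauc,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "AUC", y = "pAUC (95% specificity)",
                  colour = "candidate",
                  title = "Per-transcript discovery screening") +
    ggplot2::theme_minimal()
}

#' @describeIn stability_select selection-count profile across the three
#'   criteria, highlighting robust transcripts.
#' @param object A `stability_result`.
#' @param ... Unused.
#' @export
autoplot.stability_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("count_auc", "count_pauc", "count_wald"),
                            names_to = "criterion", names_prefix = "count_",
                            values_to = "count")
  df <- dplyr::filter(df, .data$transcript_id %in%
                        object$transcript_id[object$max_count > 0])
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$transcript_id, .data$count, max),
    y = .data$count, fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = attr(object, "min_count"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("Selections in %d bootstrap panels",
                                        attr(object, "n_stability")),
                  title = "Bootstrap stability selection") +
    ggplot2::theme_minimal()
}

#' @describeIn validate_panel per-transcript validation AUC with its
#'   stratified bootstrap confidence interval.
#' @param object A `validation_result`.
#' @param ... Unused.
#' @export
autoplot.validation_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$transcript_id, .data$auc), y = .data$auc,
    colour = .data$validated)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_auc_lower,
                                          ymax = .data$ci_auc_upper)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Validation AUC (95% stratified bootstrap CI)",
                  colour = "validated",
                  title = "Independent-cohort validation") +
    ggplot2::theme_minimal()
}
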