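# ggplot2 graphics for the package's result objects.

#' Plot a ROC curve
#'
#' Sensitivity against 1 - specificity with the chance diagonal, annotated
#' with the AUC (and its unclipped 95% CI when available); the chosen
#' cut-off's operating point is marked when set.
#'
#' @param object A `gmb_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gmb_roc
#' @export
autoplot.gmb_roc <- function(object, ...) {
  curve <- object$curve
  lab <- if (is.na(object$se)) {
    sprintf("AUC = %.3f", object$auc)
  } else {
    sprintf(
      "AUC = %.3f (95%% CI %.3f-%.3f)",
      object$auc, object$ci95[1], object$ci95[2]
    )
  }
  p <- ggplot2::ggplot(curve, ggplot2::aes(
    x = 1 - .data$specificity,
    y = .data$sensitivity
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::annotate("text", x = 0.65, y = 0.1, label = lab, size = 3.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
  if (!is.na(object$cutoff) && is.finite(object$cutoff)) {
    p <- p + ggplot2::annotate("point",
      x = 1 - object$spec_at_cutoff, y = object$sens_at_cutoff,
      colour = "#b2182b", size = 2.5
    )
  }
  p
}

#' Plot a selection report
#'
#' Stability frequency against -log10 adjusted p-value, one point per gene,
#' selected genes highlighted; the alpha and stability thresholds of the
#' report's configuration are drawn as reference lines.
#'
#' @param object A `selection_report` from [select_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_report
#' @export
autoplot.selection_report <- function(object, ...) {
  config <- attr(object, "config")
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$stability_frequency,
    y = -log10(.data$p_adjusted),
    colour = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_vline(xintercept = config$stability_threshold, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(config$alpha), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65", `TRUE` = "#b2182b")) +
    ggplot2::labs(
      x = "Stability frequency",
      y = expression(-log[10] ~ "adjusted p"),
      colour = "Selected"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' Overlaid training (out-of-fold) and validation ROC curves of a completed
#' [run_endpoint_analysis()].
#'
#' @param object A `gmb_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gmb_run
#' @export
autoplot.gmb_run <- function(object, ...) {
  if (object$status != "ok") stop_domain("run produced no model; nothing to plot")
  curves <- dplyr::bind_rows(
    tibble::add_column(object$roc_training$curve,
      set = sprintf("training (AUC %.3f)", object$roc_training$auc)
    ),
    tibble::add_column(object$roc_validation$curve,
      set = sprintf("validation (AUC %.3f)", object$roc_validation$auc)
    )
  )
  ggplot2::ggplot(curves, ggplot2::aes(
    x = 1 - .data$specificity,
    y = .data$sensitivity, colour = .data$set
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity", colour = NULL,
      title = sprintf("Endpoint: %s", object$endpoint)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
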