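# ggplot2 graphics for validation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ROC curve of a fitted model or score
#'
#' @param data A lesion table (single reader).
#' @param spec A battery row / model-spec list, or the string `"likert"` to
#'   plot the Likert score.
#' @param definition csPCa definition.
#' @param reader Reader to analyse when `data` holds several.
#' @param ... Passed to [encode_design()].
#' @return A ggplot object.
#' @export
plot_roc <- function(data, spec, definition = c("A", "B", "C"),
                     reader = NULL, ...) {
  definition <- match.arg(definition)
  rec <- analysis_records(data, reader)
  y <- label_cspca(rec$gleason_group, rec$epe, definition)
  if (is.character(spec) && length(spec) == 1 && tolower(spec) == "likert") {
    scores <- rec$likert
    label <- "Likert"
  } else {
    fit <- fit_model(rec, spec, definition, ...)
    scores <- fit$fitted
    label <- as_model_spec(spec)$name
  }
  pts <- roc_points(scores, y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s, csPCa-%s (AUC %.3f)", label, definition,
                      auc_mw(scores, y))
    ) +
    ggplot2::theme_minimal()
}

#' Bootstrap distribution behind a validation result
#'
#' Histogram of the replicate out-of-sample AUCs with the apparent and
#' corrected estimates marked.
#'
#' @param object A `lesion_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lesion_validation <- function(object, ...) {
  ggplot2::ggplot(object$boot, ggplot2::aes(x = .data$auc_orig)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$apparent_auc,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$corrected_auc,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "Replicate-fit AUC on original cohort", y = "Replicates",
      title = sprintf("%s, csPCa-%s: apparent %.3f (dashed), corrected %.3f (red)",
                      object$model_name, object$definition,
                      object$apparent_auc, object$corrected_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Bootstrap distribution of a paired AUC difference
#'
#' @param object A `lesion_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lesion_comparison <- function(object, ...) {
  df <- tibble::tibble(delta = object$boot_delta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 40, fill = "darkseagreen",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$delta_auc, colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("Replicate AUC difference (%s - %s)",
                  object$model_a, object$model_b),
      y = "Replicates",
      title = sprintf("delta AUC %.3f [%.3f, %.3f], p = %.3g",
                      object$delta_auc, object$ci_low, object$ci_high,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of corrected AUCs across the battery
#'
#' @param results Tidy validation rows (e.g. `run_study()$results`),
#'   typically filtered to one (reader, definition).
#' @return A ggplot object, one row per (model, variant) with the corrected
#'   AUC and its 95% CI.
#' @export
plot_auc_forest <- function(results) {
  results <- dplyr::mutate(
    results,
    label = ifelse(is.na(.data$seq_variant), .data$model,
                   paste0(.data$model, " (", .data$seq_variant, ")"))
  )
  results$label <- factor(results$label, levels = rev(unique(results$label)))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$corrected_auc, y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             linewidth = 0.4, size = 0.3) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::labs(x = "Optimism-corrected AUC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
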