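# ggplot2 displays: regional box charts with lobe means, attenuation
# histograms, ROC curves.

#' Box chart of a measure by subgroup with lobe means superimposed
#'
#' Total-lung distributions per subgroup as box plots, with the per-lobe
#' subgroup means overlaid as colour-coded points connected across the two
#' subgroups -- the display that makes the apico-basal gradient and the
#' subgroup separation visible at once.
#'
#' @param cohort Patient-level data frame with `outcome` and the measure
#'   column (total lung).
#' @param lobe_metrics Long lobe table (`patient_id`, `outcome`, `lobe`,
#'   measure columns), e.g. [cohort_lobe_metrics()] output; `NULL` to skip
#'   the overlay.
#' @param measure Measure column name (default `"delta_p_250"`).
#' @return A ggplot object.
#' @export
plot_lobe_profile <- function(cohort, lobe_metrics = NULL,
                              measure = "delta_p_250") {
  cohort <- as_tibble(cohort)
  p <- ggplot2::ggplot(cohort, ggplot2::aes(x = .data$outcome,
                                            y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = 1, width = 0.5) +
    ggplot2::labs(x = NULL, y = measure,
                  title = paste0(measure, ": total lung by subgroup")) +
    ggplot2::theme_minimal()
  if (!is.null(lobe_metrics)) {
    lm_means <- summarise(
      group_by(as_tibble(lobe_metrics), .data$outcome, .data$lobe),
      value = mean(.data[[measure]], na.rm = TRUE), .groups = "drop")
    p <- p +
      ggplot2::geom_line(data = lm_means,
                         ggplot2::aes(y = .data$value, colour = .data$lobe,
                                      group = .data$lobe)) +
      ggplot2::geom_point(data = lm_means,
                          ggplot2::aes(y = .data$value, colour = .data$lobe),
                          size = 2) +
      ggplot2::labs(colour = "lobe mean")
  }
  p
}

#' Plot exported attenuation histograms
#'
#' Frequency against attenuation (HU), one panel per region, inspiration
#' and expiration overlaid; the rightward expiratory shift and curve
#' broadening of collapsing lung is directly visible.
#'
#' @param histograms Output of [histogram_export()] for one or both phases
#'   (row-bound).
#' @return A ggplot object.
#' @export
plot_attenuation_histogram <- function(histograms) {
  ggplot2::ggplot(as_tibble(histograms),
                  ggplot2::aes(x = .data$bin_left + 0.5, y = .data$count,
                               colour = .data$phase)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "attenuation (HU)", y = "frequency",
                  colour = "phase") +
    ggplot2::theme_minimal()
}

#' ROC curve of a fitted prognostic model
#'
#' @param object A `hushift_logit`.
#' @param ... Unused.
#' @return A ggplot object with the empirical ROC curve and the AUC in the
#'   subtitle.
#' @method autoplot hushift_logit
#' @export
autoplot.hushift_logit <- function(object, ...) {
  scores <- fitted(object$fit)
  y <- object$fit$y
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y[ord] == 0) / sum(y == 0))
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = "ROC: death/transplantation within 3 years",
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f, DeLong)",
                         object$auc$auc, object$auc$ci_low,
                         object$auc$ci_high)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
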