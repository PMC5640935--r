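#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline
#'   geom_point geom_errorbarh geom_vline geom_density geom_col labs
#'   facet_wrap theme_minimal
NULL

#' Plot a ROC curve
#'
#' @param object An `organo_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot organo_roc
#' @export
autoplot.organo_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Forest plot of per-module odds ratios
#'
#' @param or_table The `or_table` from [run_full_study()] (or any tibble
#'   with `module`, `series`, `model`, `or`, `conf.low`, `conf.high`).
#' @return A ggplot on the log-OR axis, faceted by series and model.
#' @export
plot_or_forest <- function(or_table) {
  ggplot(or_table,
         aes(x = log(.data$or), y = .data$module)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_errorbarh(aes(xmin = log(.data$conf.low),
                       xmax = log(.data$conf.high)), height = 0.2) +
    geom_point() +
    facet_wrap(~ .data$series + .data$model) +
    labs(x = "log(OR) per unit scaled module score", y = NULL) +
    theme_minimal()
}

#' Score densities by group for an evaluated module
#'
#' @param object An `organo_module_eval` from [evaluate_module()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot organo_module_eval
#' @export
autoplot.organo_module_eval <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$score, fill = .data$group)) +
    geom_density(alpha = 0.4) +
    labs(x = "module score", y = "density",
         title = sprintf("Module score by group (AUC = %.3f%s)",
                         object$auc,
                         if (object$resubstitution) ", resubstitution"
                         else "")) +
    theme_minimal()
}

#' Stacked proportions of subtypes within each metastatic pattern
#'
#' @param object An `organo_crosstab` from [pattern_subtype_crosstab()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot organo_crosstab
#' @export
autoplot.organo_crosstab <- function(object, ...) {
  df <- as.data.frame(object$row_prop)
  ggplot(df, aes(x = .data$pattern, y = .data$Freq,
                 fill = .data$subtype)) +
    geom_col() +
    labs(x = NULL, y = "proportion of pattern") +
    theme_minimal()
}
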