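#' Plot an ROC curve
#'
#' @param object An [roc_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ogtt_roc
#' @export
autoplot.ogtt_roc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_step(direction = "hv", colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot benchmark AUCs against the reference model
#'
#' Dot-and-interval plot of model AUCs with their 95% CIs, coloured by the
#' rounded-q significance call of the DeLong comparison with the reference;
#' the reference model's AUC is drawn as a vertical line.
#'
#' @param object An `ogtt_benchmark`.
#' @param top_n Show at most this many models (by AUC), default 30.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ogtt_benchmark
#' @export
autoplot.ogtt_benchmark <- function(object, top_n = 30L, ...) {
  d <- tidy(object)
  d$significant[is.na(d$significant)] <- FALSE
  d <- utils::head(d, top_n)
  ref_auc <- object$performance$auc[
    object$performance$model_id == object$reference]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$auc,
    y = stats::reorder(.data$model_id, .data$auc),
    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = ref_auc, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "#b2182b"),
      name = "beats reference\n(rounded q < 0.05)") +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-marker correlation structure of a cohort
#'
#' Pairwise Pearson correlations between glucose time points and metabolic
#' markers, the structure the synthetic generator is calibrated against.
#'
#' @param cohort An `ogtt_cohort`.
#' @param markers Markers to include; defaults to the glucose time points
#'   and the six metabolites.
#' @return A ggplot heat map.
#' @export
plot_marker_correlations <- function(cohort,
                                     markers = c(pg_markers(),
                                                 metabolite_markers())) {
  markers <- intersect(markers, marker_names(cohort))
  cm <- stats::cor(as.data.frame(cohort[markers]),
                   use = "pairwise.complete.obs")
  d <- tibble::as_tibble(as.data.frame.table(cm, responseName = "r"))
  names(d)[1:2] <- c("marker_a", "marker_b")
  ggplot2::ggplot(d, ggplot2::aes(.data$marker_a, .data$marker_b,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
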