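# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   geom_line scale_fill_gradient2 labs theme_minimal facet_wrap
#'   stat_summary
NULL

#' @export
ggplot2::autoplot

#' Heatmap of an interregional correlation matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  long <- tidyr::expand_grid(
    voi_i = factor(object$vois, levels = object$vois),
    voi_j = factor(object$vois, levels = rev(object$vois))
  )
  long$r <- object$r[cbind(as.integer(long$voi_i),
                           match(long$voi_j, object$vois))]
  ggplot(long, aes(x = .data$voi_i, y = .data$voi_j, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac", mid = "white",
                         high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "Pearson r",
         title = sprintf("Interregional correlation (n = %d, %s months)",
                         object$n_subjects, format(object$timepoint))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Effect sizes of the pseudo-reference screen
#'
#' Bar chart of the per-VOI genotype effect size (Cohen's d, KI minus WT)
#' with the selected pseudo-reference region highlighted.
#'
#' @param object An `effect_size_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot effect_size_report
#' @export
autoplot.effect_size_report <- function(object, ...) {
  df <- tidy(object)
  df$voi <- factor(df$voi, levels = df$voi[order(abs(df$d))])
  ggplot(df, aes(x = .data$voi, y = .data$d, fill = .data$selected)) +
    geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#b2182b")) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Cohen's d (KI - WT)",
         title = sprintf("Pseudo-reference screen: %s selected",
                         object$selected_reference)) +
    theme_minimal()
}

#' Group-mean uptake trajectories
#'
#' Mean uptake over scan age per genotype/arm cell, for one tracer and a set
#' of VOIs (averaged per subject first).
#'
#' @param x Regional uptake table.
#' @param vois VOIs to average (e.g. a composite's constituents).
#' @param tracer Tracer to plot.
#' @return A ggplot.
#' @export
plot_trajectories <- function(x, vois, tracer = "TSPO") {
  df <- dplyr::filter(x, .data$tracer == !!tracer, .data$voi %in% vois)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$genotype, .data$arm, .data$age_months,
                    .data$subject_id),
    value = mean(.data$value), .groups = "drop"
  )
  unit <- unique(x$unit)
  ggplot(df, aes(x = .data$age_months, y = .data$value,
                 colour = .data$arm, group = .data$arm)) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point") +
    facet_wrap(~genotype) +
    labs(x = "age (months)", y = unit,
         title = sprintf("%s uptake, mean over %d VOIs", tracer,
                         length(vois))) +
    theme_minimal()
}
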