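feature_columns <- c("r_oi", "max_power_freq", "lat_index", "lat_strength",
                     "clustering_coef", "conn_diversity", "central_strength",
                     "central_energy", "max_tic_kurtosis")

# long format of the numeric features, finite values only
features_long <- function(table, selection = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(dplyr::filter(table, .data$candidate),
                  "subject", "component", dplyr::all_of(feature_columns)),
    cols = dplyr::all_of(feature_columns),
    names_to = "feature", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  long$selected <- FALSE
  if (!is.null(selection)) {
    sel <- dplyr::filter(selection, !is.na(.data$component))
    key <- paste(sel$subject, sel$component)
    long$selected <- paste(long$subject, long$component) %in% key
  }
  long$feature <- factor(long$feature, levels = feature_columns)
  long
}

#' Feature distributions across the cohort
#'
#' Histograms of each feature over all components and subjects, with the
#' selected (epileptic) components highlighted — the standard diagnostic
#' view of how the selected components sit in the cohort distributions.
#'
#' @param table cohort feature table.
#' @param selection optional selection tibble (from [classify_components()]).
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_feature_distributions <- function(table, selection = NULL, bins = 30) {
  long <- features_long(table, selection)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "grey30",
                            linewidth = 0.1) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "components") +
    ggplot2::theme_minimal()
  sel <- dplyr::filter(long, .data$selected)
  if (nrow(sel))
    p <- p + ggplot2::geom_rug(data = sel, colour = "red", linewidth = 0.6)
  p
}

#' Normalized-range feature boxplot
#'
#' Boxplot of all features rescaled to \[0, 1\] across the cohort, selected
#' components overplotted.
#'
#' @inheritParams plot_feature_distributions
#' @return a ggplot object.
#' @export
plot_feature_boxplot <- function(table, selection = NULL) {
  long <- features_long(table, selection)
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$feature),
    value = (.data$value - min(.data$value)) /
      max(diff(range(.data$value)), .Machine$double.eps))
  long <- dplyr::ungroup(long)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "normalized range") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  sel <- dplyr::filter(long, .data$selected)
  if (nrow(sel))
    p <- p + ggplot2::geom_point(data = sel, colour = "red", size = 1.5)
  p
}

#' @rdname plot_feature_distributions
#' @param object a `soz_classification` or `soz_cohort`.
#' @param ... unused.
#' @method autoplot soz_classification
#' @export
autoplot.soz_classification <- function(object, ...) {
  plot_feature_distributions(object$table, object$selection)
}

#' @rdname plot_feature_distributions
#' @method autoplot soz_cohort
#' @export
autoplot.soz_cohort <- function(object, ...) {
  plot_feature_distributions(object$features,
                             object$classification$selection)
}
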