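#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group summary into long per-group rows
#'
#' @param x an `adipo_group_summary`.
#' @param ... unused.
#' @return Tibble with one row per feature x group: `feature`, `group`,
#'   `mean`, `sem`, `n`, plus the shared `U`, `p_value` and `significant`.
#' @export
tidy.adipo_group_summary <- function(x, ...) {
  groups <- attr(x, "groups")
  long <- purrr::map_dfr(groups, function(g) {
    tibble(
      feature = x$feature, group = g,
      mean = x[[paste0("mean_", g)]],
      sem = x[[paste0("sem_", g)]],
      n = x[[paste0("n_", g)]]
    )
  })
  if ("p_value" %in% names(x)) {
    long <- dplyr::left_join(
      long, dplyr::select(tibble::as_tibble(x), "feature", "U", "p_value", "significant"),
      by = "feature")
  }
  long
}

#' One-line model-level summary of a group comparison
#'
#' @param x an `adipo_group_summary`.
#' @param ... unused.
#' @return One-row tibble: number of features, groups, pooled cells, and
#'   significant features at the stored alpha.
#' @export
glance.adipo_group_summary <- function(x, ...) {
  groups <- attr(x, "groups")
  n_cols <- paste0("n_", groups)
  tibble(
    n_features = nrow(x),
    n_groups = length(groups),
    n_cells = sum(unlist(x[1, n_cols])),
    n_significant = if ("significant" %in% names(x)) sum(x$significant) else NA_integer_,
    alpha = attr(x, "alpha")
  )
}

#' Plot group means with SEM error bars
#'
#' @param object an `adipo_group_summary`.
#' @param ... unused.
#' @return A ggplot: one panel per feature, mean ± SEM per group.
#' @export
autoplot.adipo_group_summary <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SEM") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-feature distributions of a feature table
#'
#' @param object an `adipo_features` tibble.
#' @param features which features to plot.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot of overlaid group histograms, one panel per feature.
#' @export
autoplot.adipo_features <- function(object,
                                    features = c("volume", "nod",
                                                 "equiv_diameter", "sphericity"),
                                    bins = 30, ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(features),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free") +
    ggplot2::labs(x = NULL, y = "adipocytes") +
    ggplot2::theme_bw()
}

#' Plot binned class distributions as group-mean bar charts
#'
#' @param object an `adipo_distribution` from [binned_distribution()].
#' @param ... unused.
#' @return A ggplot of per-class mean counts per group.
#' @export
autoplot.adipo_distribution <- function(object, ...) {
  summ <- distribution_summary(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin_lo, y = .data$mean_count,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free") +
    ggplot2::labs(x = "class (lower edge)", y = "mean adipocytes per class") +
    ggplot2::theme_bw()
}
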