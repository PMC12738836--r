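# ggplot2 visualisations. Heatmaps and line tracks orient position -300 at
# the left and -1 (the start codon) at the right.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class-level position profiles
#'
#' Line track of a group-aggregated attention or saliency profile, one facet
#' per class.
#'
#' @param object A `position_profile` tibble from [group_profile()] or
#'   [group_saliency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.position_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(colour = "#255C99") +
    ggplot2::facet_wrap(~class, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "position upstream of start codon",
      y = attr(object, "kind") %||% "value"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap rendering of class-level profiles
#'
#' @param profile A `position_profile` tibble.
#' @return A ggplot object (one row per class, colour = value).
#' @export
plot_profile_heatmap <- function(profile) {
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$position, y = .data$class, fill = .data$value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "position upstream of start codon", y = NULL,
      fill = attr(profile, "kind") %||% "value"
    ) +
    ggplot2::theme_minimal()
}

#' Plot perturbation-importance tracks
#'
#' @param object An `importance_profile` from [perturbation_importance()].
#' @param ... Unused.
#' @return A ggplot object, one facet per mutation window size.
#' @export
autoplot.importance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(colour = "#D62839") +
    ggplot2::facet_wrap(~window_size, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "position upstream of start codon",
      y = "importance (accuracy drop)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object A `leader_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch.
#' @export
autoplot.leader_fit <- function(object, ...) {
  h <- tidy(object) %>%
    tidyr::pivot_longer(
      c("train_loss", "train_acc", "val_loss", "val_acc"),
      names_to = "series", values_to = "value"
    ) %>%
    tidyr::separate("series", into = c("split", "measure"), sep = "_")
  ggplot2::ggplot(
    h, ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$split)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot ROC and precision-recall curves
#'
#' @param object A `metrics_report` with curve points.
#' @param ... Unused.
#' @return A ggplot with ROC and PR panels.
#' @export
autoplot.metrics_report <- function(object, ...) {
  if (is.null(object$roc_curve)) {
    abort("report carries no curve points (single-class truth?)")
  }
  roc <- object$roc_curve %>% mutate(panel = "ROC") %>%
    rename(x = "fpr", y = "tpr")
  pr <- object$pr_curve %>% mutate(panel = "Precision-recall") %>%
    select(x = "recall", y = "precision", "panel")
  ggplot2::ggplot(bind_rows(roc[, c("x", "y", "panel")], pr),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "#255C99") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
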