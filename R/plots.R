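#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_abline
#'   geom_col labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot training curves
#'
#' Loss and accuracy per epoch for the training (and, if recorded,
#' validation) split of a fitted network.
#'
#' @param object An `rtcp_dcnn`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot rtcp_dcnn
autoplot.rtcp_dcnn <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(dplyr::any_of(c("train_loss", "train_acc",
                                        "val_loss", "val_acc")),
                        names_to = c("split", "metric"), names_sep = "_",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot(h, aes(x = .data$epoch, y = .data$value, colour = .data$split)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL,
         title = "Training history") +
    theme_minimal()
}

#' Plot per-fold ROC curves of a cross-validation report
#'
#' @param object An `rtcp_cv`.
#' @param ... Unused.
#' @return A ggplot with one step curve per fold and the chance diagonal.
#' @export
#' @method autoplot rtcp_cv
autoplot.rtcp_cv <- function(object, ...) {
  ggplot(object$roc,
         aes(x = .data$fpr, y = .data$tpr, group = .data$fold,
             colour = factor(.data$fold))) +
    geom_step(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    labs(x = "false positive rate", y = "true positive rate",
         colour = "fold",
         title = sprintf("%d-fold ROC, %s (mean AUC %.3f)", object$k,
                         object$classifier, mean(object$fold_auc))) +
    theme_minimal()
}

#' Scree plot of a fitted reducer
#'
#' @param object An `rtcp_reducer`.
#' @param ... Unused.
#' @return A ggplot of per-component variance explained.
#' @export
#' @method autoplot rtcp_reducer
autoplot.rtcp_reducer <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot(d, aes(x = as.integer(.data$component), y = .data$var_explained)) +
    geom_col(fill = "steelblue") +
    labs(x = "principal component", y = "fraction of variance",
         title = sprintf("PCA spectrum (%d components, %.1f%% retained)",
                         object$d_out, 100 * sum(d$var_explained))) +
    theme_minimal()
}

#' Compare amino-acid composition between sample groups
#'
#' Mean composition per group, as used to contrast stably misclassified
#' proteins with correctly classified members of their class.
#'
#' @param data Data frame with columns `seq` and a grouping column.
#' @param group Name of the grouping column (default `"label"`).
#' @return A ggplot of grouped mean frequencies per residue.
#' @export
plot_composition <- function(data, group = "label") {
  stopifnot(is.data.frame(data), "seq" %in% names(data), group %in% names(data))
  comp <- purrr::map(data$seq, amino_acid_composition)
  d <- as_tibble(do.call(rbind, comp))
  d$group <- factor(data[[group]])
  long <- tidyr::pivot_longer(d, -"group", names_to = "residue",
                              values_to = "freq") |>
    dplyr::group_by(.data$group, .data$residue) |>
    dplyr::summarise(freq = mean(.data$freq), .groups = "drop")
  ggplot(long, aes(x = .data$residue, y = .data$freq, fill = .data$group)) +
    geom_col(position = "dodge") +
    labs(x = "amino acid", y = "mean frequency", fill = group,
         title = "Amino-acid composition by group") +
    theme_minimal()
}
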