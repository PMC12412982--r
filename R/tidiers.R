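#' @export
tidy.biogl_cv <- function(x, ...) {
  x$folds |>
    tidyr::pivot_longer(c("accuracy", "specificity", "sensitivity", "f1", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("fold", "n_test", "metric", "value")
}

#' @export
glance.biogl_cv <- function(x, ...) {
  dplyr::mutate(x$summary, k = x$k, n = nrow(x$scores), .before = 1)
}

#' @export
tidy.biogl_gcn <- function(x, ...) {
  if (!x$trained) stop_validation("model is not trained")
  x$history
}

#' @export
glance.biogl_gcn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    epochs = x$config$epochs,
    n_train = x$n_train,
    n_genes = length(x$gene_ids),
    ablation = x$config$ablation,
    L1 = last$L1, L2 = last$L2, total = last$total
  )
}

#' ROC curves of a cross-validation result
#'
#' @param object A `biogl_cv` object.
#' @param ... Unused.
#' @return A ggplot: one ROC curve per fold plus the chance diagonal.
#' @export
autoplot.biogl_cv <- function(object, ...) {
  pts <- object$scores |>
    dplyr::group_by(.data$fold) |>
    dplyr::reframe(roc_points(.data$label, .data$score))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = factor(.data$fold))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold",
                  title = sprintf("%d-fold cross-validated ROC (mean AUC %.3f)",
                                  object$k, object$summary$auc)) +
    ggplot2::theme_minimal()
}

#' Training-loss curves of a fitted model
#'
#' @param object A trained `biogl_gcn`.
#' @param ... Unused.
#' @return A ggplot of the graph-learning, classification and joint losses
#'   per epoch.
#' @export
autoplot.biogl_gcn <- function(object, ...) {
  if (!object$trained) stop_validation("model is not trained")
  df <- object$history |>
    tidyr::pivot_longer(c("L1", "L2", "total"),
                        names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Gene-frequency bar plot
#'
#' @param frequencies Tibble from [gene_frequencies()].
#' @param top_n Show the `top_n` highest-frequency genes. Default 30.
#' @return A ggplot.
#' @export
plot_gene_frequencies <- function(frequencies, top_n = 30) {
  df <- frequencies |>
    dplyr::slice_max(.data$normalized, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene_id, .data$normalized),
                                   y = .data$normalized)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized enrichment frequency") +
    ggplot2::theme_minimal()
}
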