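#' Stratified (optionally grouped) fold assignment
#'
#' Assigns samples to `k` cross-validation folds, stratifying by class. When
#' `group_id` is present (e.g. the drug each profile came from) all samples
#' of a group are kept in the same fold, and groups are stratified by their
#' majority label and balanced by size — this prevents profiles of the same
#' drug from leaking across the train/test boundary.
#'
#' @param labels Tibble with columns `sample_id`, `label` and optionally
#'   `group_id`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param grouped Use grouped splitting when `group_id` is present? Default
#'   `TRUE`.
#' @return Integer vector of fold ids (1..k) aligned to `labels` rows.
#' @export
make_folds <- function(labels, k = 5, seed = 1, grouped = TRUE) {
  stopifnot(k >= 2, all(labels$label %in% c(0, 1)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(labels)
  fold <- integer(n)
  if (grouped && "group_id" %in% colnames(labels)) {
    groups <- labels |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(glabel = as.integer(mean(.data$label) >= 0.5),
                       gsize = dplyr::n(), .groups = "drop")
    gfold <- setNames(integer(nrow(groups)), groups$group_id)
    for (cl in unique(groups$glabel)) {
      sub <- groups[groups$glabel == cl, ]
      sub <- sub[sample.int(nrow(sub)), ]
      sub <- sub[order(-sub$gsize), ]
      sizes <- numeric(k)
      for (i in seq_len(nrow(sub))) {
        target <- which.min(sizes)
        gfold[[sub$group_id[[i]]]] <- target
        sizes[[target]] <- sizes[[target]] + sub$gsize[[i]]
      }
    }
    fold <- unname(gfold[labels$group_id])
  } else {
    for (cl in c(0, 1)) {
      idx <- which(labels$label == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  for (f in seq_len(k)) {
    cls <- unique(labels$label[fold == f])
    if (length(cls) < 2) {
      stop_validation(sprintf(
        "fold %d contains a single class; provide more balanced labels or groups for stratification",
        f))
    }
  }
  fold
}

#' Cross-validated training and evaluation
#'
#' Runs stratified k-fold cross-validation of the graph-learning classifier:
#' each fold's model is trained on the remaining folds and scored on the held
#' out fold; per-fold and mean accuracy, specificity, sensitivity, F1 and AUC
#' are reported (decision threshold 0.5).
#'
#' @param X Samples-by-genes expression matrix.
#' @param labels Tibble with `sample_id`, `label` and optionally `group_id`
#'   (drug identifiers; grouped splitting is the default when present, so
#'   profiles of one drug never straddle a train/test boundary).
#' @param A Gene-gene adjacency prior.
#' @param frequencies Gene-frequency tibble or named vector
#'   ([gene_frequencies()]).
#' @param config A [model_config()].
#' @param k Number of folds, default 5.
#' @param seed Integer seed driving fold assignment and per-fold training.
#' @param grouped Use grouped splitting when `group_id` is present?
#' @param keep_models Keep the trained fold models? Default `TRUE`.
#' @return A `biogl_cv` object: list with `folds` (per-fold metric tibble),
#'   `summary` (mean metrics), `scores` (per-sample held-out scores) and
#'   `models`.
#' @export
run_cross_validation <- function(X, labels, A, frequencies,
                                 config = model_config(), k = 5, seed = 1,
                                 grouped = TRUE, keep_models = TRUE) {
  labels <- align_labels(labels, X)
  fold <- make_folds(labels, k = k, seed = seed, grouped = grouped)
  fold_metrics <- vector("list", k)
  models <- vector("list", k)
  scores_tbl <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    fit <- fit_biogl_gcn(X[train_idx, , drop = FALSE], labels$label[train_idx],
                         A, frequencies, config,
                         seed = (as.integer(seed) + 1000L * f) %% .Machine$integer.max)
    sc <- predict(fit, X[test_idx, , drop = FALSE], type = "score")
    m <- compute_metrics(labels$label[test_idx], sc)
    fold_metrics[[f]] <- dplyr::mutate(m, fold = f, n_test = length(test_idx),
                                       .before = 1)
    scores_tbl[[f]] <- tibble(sample_id = labels$sample_id[test_idx],
                              fold = f, label = labels$label[test_idx],
                              score = unname(sc))
    if (keep_models) models[[f]] <- fit
  }
  folds <- dplyr::bind_rows(fold_metrics)
  summary <- folds |>
    dplyr::summarise(dplyr::across(c("accuracy", "specificity", "sensitivity",
                                     "f1", "auc"), mean))
  out <- list(folds = folds, summary = summary,
              scores = dplyr::bind_rows(scores_tbl),
              models = if (keep_models) models else NULL,
              k = k, seed = seed, config = config)
  class(out) <- "biogl_cv"
  out
}

#' @export
print.biogl_cv <- function(x, ...) {
  cat(sprintf("<biogl_cv> %d-fold cross-validation (%s model)\n",
              x$k, x$config$ablation))
  cat("mean metrics:\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
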