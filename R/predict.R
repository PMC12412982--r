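#' DILI scores for new compound profiles
#'
#' Scores each profile with the trained model's positive-class probability
#' (the DILI score) and bins it: `high` risk above 0.8, `low` risk below 0.4,
#' `intermediate` otherwise. Input genes are reordered to the model's gene
#' order by identifier; any model gene absent from the input is an error.
#'
#' @param model A trained `biogl_gcn` model.
#' @param profiles Samples-by-genes expression matrix (e.g. MODZ-collapsed
#'   relative-expression signatures from [relative_expression()]).
#' @return A tibble with columns `compound_id`, `score`, `bin`.
#' @export
predict_dili <- function(model, profiles) {
  score <- predict(model, profiles, type = "score")
  tibble(
    compound_id = rownames(profiles) %||% paste0("compound_", seq_along(score)),
    score = unname(score),
    bin = dili_bin(score)
  )
}

dili_bin <- function(score) {
  dplyr::case_when(
    score > 0.8 ~ "high",
    score < 0.4 ~ "low",
    TRUE ~ "intermediate"
  )
}

#' Penultimate-layer feature export
#'
#' Deterministically extracts the activations of the last hidden fully
#' connected layer (the layer feeding the softmax) for each input profile —
#' the representation typically used for downstream embedding/visualization.
#'
#' @param model A trained `biogl_gcn` model.
#' @param profiles Samples-by-genes expression matrix.
#' @param path Optional TSV output path (sample ids in the first column).
#' @return M x F numeric matrix, F = width of the second-to-last fully
#'   connected layer.
#' @export
export_features <- function(model, profiles, path = NULL) {
  stopifnot(inherits(model, "biogl_gcn"))
  missing <- setdiff(model$gene_ids, toupper(colnames(profiles)))
  if (length(missing) > 0) {
    stop_validation(paste0("input is missing model gene(s): ",
                           paste(head(missing, 20), collapse = ", ")))
  }
  colnames(profiles) <- toupper(colnames(profiles))
  X <- profiles[, model$gene_ids, drop = FALSE]
  S <- model$S %||% model$S_fixed
  fw <- cls_forward(model$params, model$bn_state, X, S, model$config,
                    training = FALSE)
  feats <- fw$cache$A2
  rownames(feats) <- rownames(X)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  if (!is.null(path)) {
    df <- data.frame(sample_id = rownames(feats) %||% seq_len(nrow(feats)),
                     feats, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  feats
}

#' Save a trained model checkpoint
#'
#' Serializes the configuration, trained weights, batch-normalization state,
#' gene ordering, frozen frequency vector and frozen learned graph to a
#' single file.
#'
#' @param model A trained `biogl_gcn`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "biogl_gcn"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `biogl_gcn` model.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "biogl_gcn")) stop_format("not a biogl_gcn checkpoint")
  model
}
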