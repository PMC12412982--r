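#' Call differentially expressed genes from one profile
#'
#' A gene is differentially expressed in a normalized (z-score-like)
#' transcriptional profile when the absolute value of its expression meets or
#' exceeds `threshold`. The default of 2 follows the signature-strength
#' convention used for L1000-style profiles.
#'
#' @param profile Named numeric vector, one value per gene.
#' @param threshold Nonnegative cutoff on `abs(profile)`; boundary inclusive.
#' @return Character vector of gene ids called as DEGs.
#' @export
call_degs <- function(profile, threshold = 2) {
  stopifnot(is.numeric(profile), threshold >= 0)
  if (is.null(names(profile))) stop_validation("profile must be a named vector")
  names(profile)[abs(profile) >= threshold]
}

#' Count enriched biological-process terms for one DEG set
#'
#' With the significance filter disabled (the intended use: p- and q-value
#' cutoffs of 1), a term counts as enriched for a profile as soon as it shares
#' at least one gene with the profile's DEG set. For each gene, `t` counts the
#' enriched terms that contain it — a gene outside the DEG set counts 0, since
#' enrichment output lists only the DEG/term overlap.
#'
#' @param deg_set Character vector of DEG ids (may be empty).
#' @param gene_sets A [gene_set_collection()].
#' @param gene_ids Gene universe defining the order of the returned counts.
#' @return List with `t` (named integer vector over `gene_ids`) and `tau`
#'   (number of enriched terms).
#' @export
count_enrichment <- function(deg_set, gene_sets, gene_ids) {
  deg_set <- toupper(deg_set)
  gene_ids <- toupper(gene_ids)
  t_i <- setNames(integer(length(gene_ids)), gene_ids)
  enriched <- vapply(gene_sets, function(s) length(intersect(s, deg_set)) > 0, logical(1))
  tau <- sum(enriched)
  if (tau > 0) {
    hits <- table(unlist(lapply(unclass(gene_sets)[enriched],
                                function(s) intersect(s, deg_set))))
    common <- intersect(names(hits), gene_ids)
    t_i[common] <- as.integer(hits[common])
  }
  list(t = t_i, tau = tau)
}

#' Enrichment counts for a set of profiles
#'
#' Runs DEG calling and enrichment counting for every row (profile) of an
#' expression matrix, producing the count matrix behind the gene-frequency
#' vector. Each profile is one observation `j`; `t[j, i]` is the number of
#' terms enriched for profile `j` that contain gene `i`, and `tau[j]` the
#' total number of enriched terms.
#'
#' @param mat Samples-by-genes expression matrix (normalized values).
#' @param gene_sets A [gene_set_collection()].
#' @param threshold DEG threshold passed to [call_degs()].
#' @return An `enrichment_counts` object: list with integer matrix `t`
#'   (profiles x genes), integer vector `tau` and `gene_ids`.
#' @export
enrichment_counts <- function(mat, gene_sets, threshold = 2) {
  validate_expression(mat)
  gene_ids <- colnames(mat)
  res <- lapply(seq_len(nrow(mat)), function(j) {
    degs <- call_degs(mat[j, ], threshold)
    count_enrichment(degs, gene_sets, gene_ids)
  })
  t_mat <- do.call(rbind, lapply(res, `[[`, "t"))
  rownames(t_mat) <- rownames(mat)
  tau <- vapply(res, `[[`, numeric(1), "tau")
  out <- list(t = t_mat, tau = as.integer(tau), gene_ids = gene_ids)
  class(out) <- "enrichment_counts"
  out
}

#' Per-gene enrichment frequencies
#'
#' The raw frequency of gene `i` is the average over profiles of the number of
#' enriched terms containing it: `p_i = sum_j t[j, i] / M`. Raw frequencies
#' are then min-max normalized to \[0, 1\] for use in the graph-learning
#' layer.
#'
#' @param counts An `enrichment_counts` object.
#' @return A tibble with columns `gene_id`, `raw`, `normalized`.
#' @export
compute_frequencies <- function(counts) {
  stopifnot(inherits(counts, "enrichment_counts"))
  M <- nrow(counts$t)
  if (is.null(M) || M == 0) stop_validation("at least one profile is required")
  raw <- colSums(counts$t) / M
  tibble(
    gene_id = counts$gene_ids,
    raw = unname(raw),
    normalized = normalize_frequencies(unname(raw))
  )
}

#' Min-max normalization of a frequency vector
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros. The result
#' is invariant to positive affine rescaling of the input.
#'
#' @param raw Numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_frequencies <- function(raw) {
  stopifnot(is.numeric(raw))
  rng <- range(raw)
  if (diff(rng) == 0) return(rep(0, length(raw)))
  (raw - rng[[1]]) / diff(rng)
}

#' Gene frequencies from expression and gene sets in one call
#'
#' Convenience pipeline: DEG calling, enrichment counting and frequency
#' normalization.
#'
#' @inheritParams enrichment_counts
#' @return A tibble with columns `gene_id`, `raw`, `normalized`.
#' @export
gene_frequencies <- function(mat, gene_sets, threshold = 2) {
  compute_frequencies(enrichment_counts(mat, gene_sets, threshold))
}

# Align a frequency tibble (or named vector) to a gene ordering; missing genes
# are an error since the frequency vector must cover the graph's node set.
align_frequencies <- function(freq, gene_ids) {
  if (is.data.frame(freq)) {
    v <- setNames(freq$normalized, toupper(freq$gene_id))
  } else {
    v <- freq
    names(v) <- toupper(names(v))
  }
  missing <- setdiff(toupper(gene_ids), names(v))
  if (length(missing) > 0) {
    stop_validation(paste0("no frequency for gene(s): ",
                           paste(head(missing, 10), collapse = ", ")))
  }
  unname(v[toupper(gene_ids)])
}
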