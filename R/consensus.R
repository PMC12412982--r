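#' MODZ consensus signature of replicate profiles
#'
#' Collapses R replicate expression profiles into one consensus signature by
#' the moderated z-score (MODZ) weighting used in the L1000 pipeline: the
#' pairwise Spearman correlation matrix between replicates is computed with
#' the diagonal set to 0, each replicate's raw weight is the sum of its
#' correlations to the other replicates, weights are floored at a small
#' positive constant (so an uncorrelated or rank-reversed outlier is
#' down-weighted, never sign-flipped) and normalized to sum to 1, and the
#' consensus is the weighted linear combination of the replicates.
#'
#' @param profiles Replicates-by-genes numeric matrix (R x N, R >= 1, N >= 2).
#' @param compound_id Optional compound identifier carried through.
#' @param weight_floor Lower bound applied to raw weights before
#'   normalization. Default 0.01.
#' @return A `consensus_signature`: list with `values` (length-N named
#'   numeric), `weights` (length-R, summing to 1) and `compound_id`.
#' @export
modz_consensus <- function(profiles, compound_id = NULL, weight_floor = 0.01) {
  if (is.vector(profiles)) profiles <- matrix(profiles, nrow = 1,
                                              dimnames = list(NULL, names(profiles)))
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  R <- nrow(profiles)
  N <- ncol(profiles)
  if (R < 1) stop_validation("at least one replicate is required")
  if (R == 1) {
    out <- list(values = profiles[1, ], weights = 1, compound_id = compound_id)
    class(out) <- "consensus_signature"
    return(out)
  }
  if (N < 2) stop_validation("Spearman weighting needs at least 2 genes")
  rho <- suppressWarnings(cor(t(profiles), method = "spearman"))
  rho[is.na(rho)] <- 0  # zero-variance replicate: undefined correlation -> no support
  diag(rho) <- 0
  w_raw <- rowSums(rho)
  w <- pmax(w_raw, weight_floor)
  w <- w / sum(w)
  out <- list(
    values = colSums(w * profiles),
    weights = w,
    raw_weights = w_raw,
    compound_id = compound_id
  )
  class(out) <- "consensus_signature"
  out
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf("<consensus_signature> %d genes; weights: %s\n",
              length(x$values), paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

#' Relative expression of a compound against control
#'
#' Log2 ratio of the compound's consensus signature to the control consensus,
#' per gene, with a small pseudocount guarding against zero FPKM values:
#' `log2((cs_ingredient + epsilon) / (cs_control + epsilon))`.
#'
#' @param cs_ingredient,cs_control `consensus_signature` objects or
#'   nonnegative numeric vectors with aligned gene order.
#' @param epsilon Pseudocount in expression units. Default 0.01.
#' @return Numeric vector of per-gene log2 ratios.
#' @export
relative_expression <- function(cs_ingredient, cs_control, epsilon = 0.01) {
  a <- if (inherits(cs_ingredient, "consensus_signature")) cs_ingredient$values else cs_ingredient
  b <- if (inherits(cs_control, "consensus_signature")) cs_control$values else cs_control
  stopifnot(length(a) == length(b), epsilon > 0)
  if (any(a < 0) || any(b < 0)) {
    stop_validation("relative_expression expects nonnegative (FPKM-like) values")
  }
  log2((a + epsilon) / (b + epsilon))
}
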