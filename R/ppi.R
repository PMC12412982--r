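#' Build a gene-gene adjacency prior from scored edges
#'
#' Places STRING-style confidence scores into a symmetric N x N matrix over a
#' fixed gene ordering; pairs without a recorded interaction are 0. Edges with
#' an endpoint outside `gene_order` are dropped (with a message), so the
#' full landmark-gene set can be kept as the node set even when the links file
#' covers only part of it — such genes end up with only their self-loop once
#' [add_self_loops()] is applied.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `score`
#'   (as returned by [read_string_links()]).
#' @param gene_order Character vector of gene ids fixing row/column order.
#' @return A symmetric numeric matrix with zero diagonal and dimnames
#'   `gene_order`.
#' @export
build_adjacency <- function(edges, gene_order) {
  if (length(gene_order) == 0) stop_validation("gene_order must be nonempty")
  gene_order <- toupper(gene_order)
  if (anyDuplicated(gene_order)) stop_validation("gene_order contains duplicates")
  n <- length(gene_order)
  A <- matrix(0, n, n, dimnames = list(gene_order, gene_order))
  if (nrow(edges) > 0) {
    ia <- match(toupper(edges$gene_a), gene_order)
    ib <- match(toupper(edges$gene_b), gene_order)
    keep <- !is.na(ia) & !is.na(ib)
    if (any(!keep)) {
      inform(sprintf("build_adjacency: dropped %d edge(s) with endpoints outside gene_order",
                     sum(!keep)))
    }
    if (any(keep)) {
      A[cbind(ia[keep], ib[keep])] <- edges$score[keep]
      A[cbind(ib[keep], ia[keep])] <- edges$score[keep]
    }
  }
  A
}

#' Insert unit self-loops into an adjacency matrix
#'
#' Sets every diagonal element to exactly 1 so each node retains its own
#' features during graph convolution; off-diagonal entries are untouched.
#' Idempotent.
#'
#' @param A Square numeric adjacency matrix.
#' @return The matrix with unit diagonal.
#' @export
add_self_loops <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  diag(A) <- 1
  A
}

#' Elementwise power of an adjacency matrix
#'
#' Raises each entry to the power `phi`. For entries in (0, 1) and `phi` > 1
#' this magnifies the contrast between strong and weak interactions while
#' leaving zeros, ones (including self-loops) and the support unchanged.
#'
#' @param A Adjacency matrix with entries in \[0, 1\].
#' @param phi Positive exponent.
#' @return `A ^ phi`, elementwise.
#' @export
power_adjacency <- function(A, phi) {
  stopifnot(is.matrix(A))
  if (!is.numeric(phi) || length(phi) != 1 || phi <= 0) {
    stop_validation("phi must be a positive number")
  }
  A^phi
}

#' Summary statistics of a (learned) gene graph
#'
#' Symmetrizes the matrix, removes self-loops, binarizes the off-diagonal
#' entries at `edge_threshold` (entries `>= edge_threshold` and `> 0` become
#' edges) and reports the global clustering coefficient (transitivity:
#' 3 x triangles / connected triples) and the undirected graph density.
#'
#' @param S Square numeric matrix, e.g. a learned graph.
#' @param edge_threshold Binarization threshold; defaults to the mean
#'   off-diagonal value of the symmetrized matrix.
#' @return A tibble with columns `clustering_coefficient`, `density`,
#'   `n_nodes`, `n_edges`, `edge_threshold`.
#' @export
graph_stats <- function(S, edge_threshold = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- nrow(S)
  W <- (S + t(S)) / 2
  diag(W) <- 0
  if (is.null(edge_threshold)) {
    off <- W[upper.tri(W)]
    edge_threshold <- if (length(off) > 0) mean(off) else 0
  }
  stopifnot(edge_threshold >= 0)
  Adj <- (W >= edge_threshold & W > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(Adj, mode = "undirected", diag = FALSE)
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc) || is.na(cc)) cc <- 0
  dens <- if (n > 1) igraph::edge_density(g) else 0
  tibble(
    clustering_coefficient = cc,
    density = dens,
    n_nodes = n,
    n_edges = igraph::ecount(g),
    edge_threshold = edge_threshold
  )
}

#' Export an adjacency or learned graph as an edge list
#'
#' @param A Square matrix with gene dimnames.
#' @param path Output TSV path.
#' @param include_self_loops Keep diagonal entries? Default `FALSE`.
#' @return The edge tibble, invisibly written to `path` when given.
#' @export
write_edge_list <- function(A, path = NULL, include_self_loops = FALSE) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  idx <- which(A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  if (!include_self_loops) idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  edges <- tibble(
    gene_a = ids[idx[, 1]],
    gene_b = ids[idx[, 2]],
    weight = A[idx]
  ) |> dplyr::arrange(.data$gene_a, .data$gene_b)
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edges)
}

#' Read a dense adjacency matrix written as TSV
#'
#' @param path TSV with gene ids in the first column and as header.
#' @return Symmetric numeric matrix.
#' @export
read_adjacency_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  A <- as.matrix(df)
  if (nrow(A) != ncol(A) || !isTRUE(all.equal(A, t(A), tolerance = 1e-8))) {
    stop_format("adjacency TSV is not a symmetric square matrix")
  }
  rownames(A) <- toupper(rownames(A))
  colnames(A) <- toupper(colnames(A))
  A
}

#' Write a dense adjacency matrix as TSV
#'
#' @param A Square matrix with gene dimnames.
#' @param path Output path.
#' @export
write_adjacency_matrix <- function(A, path) {
  df <- data.frame(gene_id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
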