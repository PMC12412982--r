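# Scalar nonlinearities shared by the graph-learning layer and the network.
# tanh is the layer default: it is smooth at 0, where the graph-attention
# vector alpha starts, and bounds the argument of the exponential.
activation_fun <- function(name) {
  switch(name,
    relu = function(x) pmax(x, 0),
    tanh = tanh,
    identity = identity,
    stop_validation(paste0("unknown activation: ", name))
  )
}

activation_grad <- function(name) {
  switch(name,
    relu = function(x) (x > 0) * 1,
    tanh = function(x) 1 - tanh(x)^2,
    identity = function(x) rep(1, length(x)) |> array(dim = dim(x) %||% length(x)),
    stop_validation(paste0("unknown activation: ", name))
  )
}

EXP_CLIP <- 50  # exp() argument clamp; inactive at reasonable scales

#' Project cross-sample gene vectors to a low-dimensional space
#'
#' Each gene is represented by its expression across the samples used to
#' learn the graph (row `i` of `gene_vectors` is gene `i` across K samples)
#' and mapped to `d` dimensions by a projection matrix: `g_tilde = G W_g`.
#'
#' @param gene_vectors N x K numeric matrix of per-gene expression vectors.
#' @param W_g K x d projection matrix.
#' @return N x d matrix of projected gene representations.
#' @export
project_genes <- function(gene_vectors, W_g) {
  stopifnot(is.matrix(gene_vectors), is.matrix(W_g))
  if (ncol(gene_vectors) != nrow(W_g)) {
    stop_validation(sprintf("projection mismatch: gene_vectors has %d columns, W_g has %d rows",
                            ncol(gene_vectors), nrow(W_g)))
  }
  gene_vectors %*% W_g
}

#' Learn a row-stochastic gene graph from a biological prior
#'
#' The learned graph combines the powered adjacency prior with a
#' frequency-weighted distance between projected gene representations:
#'
#' \deqn{S_{ij} = \frac{A^\phi_{ij}\,\exp(\sigma(\alpha^T
#'   ((p_i-p_j)(\tilde g_i-\tilde g_j))))}{\sum_j A^\phi_{ij}\,
#'   \exp(\sigma(\cdot))}}
#'
#' The softmax-style normalization makes every row of S sum to 1 with
#' nonnegative entries, and multiplication by the prior keeps the support of
#' S inside the support of `A_phi` — genes without a prior interaction can
#' never gain one.
#'
#' @param g_tilde N x d matrix of projected gene vectors ([project_genes()]).
#' @param p Length-N normalized gene frequency vector.
#' @param A_phi N x N powered adjacency prior with unit diagonal
#'   ([power_adjacency()] after [add_self_loops()]).
#' @param alpha Length-d learnable weight vector.
#' @param activation Name of the scalar nonlinearity sigma; one of
#'   `"tanh"` (default), `"relu"`, `"identity"`.
#' @return N x N row-stochastic matrix S, dimnames inherited from `A_phi`.
#' @export
compute_learned_graph <- function(g_tilde, p, A_phi, alpha,
                                  activation = "tanh") {
  stopifnot(is.matrix(g_tilde), is.matrix(A_phi), nrow(A_phi) == ncol(A_phi))
  n <- nrow(A_phi)
  stopifnot(nrow(g_tilde) == n, length(p) == n, length(alpha) == ncol(g_tilde))
  if (any(rowSums(A_phi != 0) == 0)) {
    stop_validation("A_phi has an all-zero row; add self-loops before learning the graph")
  }
  sigma <- activation_fun(activation)
  q <- as.numeric(g_tilde %*% alpha)                 # q_i = alpha' g_tilde_i
  u <- outer(p, p, "-") * outer(q, q, "-")           # u_ij = (p_i-p_j)(q_i-q_j)
  f <- pmin(pmax(sigma(u), -EXP_CLIP), EXP_CLIP)
  E <- A_phi * exp(f)
  S <- E / rowSums(E)
  dimnames(S) <- dimnames(A_phi)
  S
}

#' Graph-learning loss
#'
#' \deqn{L_1 = \sum_{i,j} \|(p_i-p_j)(\tilde g_i-\tilde g_j)\|_2^2\, S_{ij}
#'   + \gamma \|S\|_F^2 + \beta \|S - A^\phi\|_F^2}
#'
#' The first term asks the learned graph to place weight on gene pairs that
#' are close in the frequency-weighted projected space, the second controls
#' the sparsity/spread of S, and the third anchors S to the biological prior.
#'
#' @inheritParams compute_learned_graph
#' @param S N x N learned graph.
#' @param gamma,beta Nonnegative regularization weights.
#' @return Nonnegative scalar.
#' @export
graph_learning_loss <- function(S, g_tilde, p, A_phi, gamma, beta) {
  n <- nrow(S)
  stopifnot(ncol(S) == n, nrow(g_tilde) == n, length(p) == n,
            all(dim(A_phi) == dim(S)), gamma >= 0, beta >= 0)
  D <- pairwise_weighted_dist2(g_tilde, p)
  sum(D * S) + gamma * sum(S^2) + beta * sum((S - A_phi)^2)
}

# ||(p_i - p_j)(g_i - g_j)||^2 for all pairs, i.e. (p_i-p_j)^2 * ||g_i-g_j||^2.
# When p is NULL (frequency-free ablation) the (p_i-p_j) factor is 1.
pairwise_weighted_dist2 <- function(g_tilde, p = NULL) {
  sq <- rowSums(g_tilde^2)
  G2 <- outer(sq, sq, "+") - 2 * tcrossprod(g_tilde)
  G2[G2 < 0] <- 0  # clamp numerical negatives
  if (is.null(p)) G2 else outer(p, p, "-")^2 * G2
}
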