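# Independent brute-force oracles. These deliberately use scalar loops and
# first-principles definitions so they share no code path with the package.

oracle_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# L1 = sum_ij ||(p_i-p_j)(g_i-g_j)||^2 S_ij + gamma ||S||_F^2 + beta ||S-A||_F^2
oracle_graph_loss <- function(S, g, p, A_phi, gamma, beta) {
  n <- nrow(S)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- (p[i] - p[j]) * (g[i, ] - g[j, ])
      acc <- acc + sum(v^2) * S[i, j]
    }
  }
  fro2 <- function(M) { s <- 0; for (x in M) s <- s + x^2; s }
  acc + gamma * fro2(S) + beta * fro2(S - A_phi)
}

oracle_cross_entropy <- function(z, y) {
  acc <- 0
  for (i in seq_along(z)) {
    zi <- min(max(z[i], 1e-7), 1 - 1e-7)
    acc <- acc + if (y[i] == 1) log(zi) else log(1 - zi)
  }
  -acc / length(z)
}

# AUC by exhaustive positive-negative pair enumeration, ties half credit
oracle_auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# global clustering coefficient by exhaustive triangle / connected-triple count
oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && adj[i, j] == 1 && adj[j, k] == 1) {
      triples <- triples + 1                 # path i-j-k centred at j
      if (adj[i, k] == 1) triangles <- triangles + 1
    }
  }
  if (triples == 0) 0 else triangles / triples  # = 3*tri / connected triples
}

# Eq.-1 frequencies by a per-gene / per-profile / per-term triple loop
oracle_frequencies <- function(deg_sets, sets, gene_ids) {
  M <- length(deg_sets)
  raw <- setNames(numeric(length(gene_ids)), gene_ids)
  for (g in gene_ids) {
    total <- 0
    for (j in seq_len(M)) {
      for (term in sets) {
        enriched <- length(intersect(term, deg_sets[[j]])) > 0
        if (enriched && g %in% term && g %in% deg_sets[[j]]) total <- total + 1
      }
    }
    raw[g] <- total / M
  }
  raw
}

# a small random symmetric adjacency with unit diagonal over gene_ids
toy_adjacency <- function(gene_ids, edge_prob = 0.4, seed = 1) {
  n <- length(gene_ids)
  set.seed(seed)
  A <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < edge_prob) A[i, j] <- A[j, i] <- runif(1, 0.7, 1)
  }
  # guarantee no isolated rows beyond the self-loop
  add_self_loops(A)
}

quick_config <- function(...) {
  args <- modifyList(list(hidden_dims_gcn = c(4, 3), hidden_dims_fc = c(16, 8, 2),
                          d = 4, epochs = 10), list(...))
  do.call(model_config, args)
}

bench_config <- function(...) {
  args <- modifyList(list(hidden_dims_gcn = c(16, 8), hidden_dims_fc = c(64, 32, 2)),
                     list(...))
  do.call(model_config, args)
}
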