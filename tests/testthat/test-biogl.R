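test_that("gene projection is an exact matrix product", {
  gv <- matrix(rnorm(12), 4, 3)
  sel <- diag(3)[, 1:2]                      # first-two-columns selector
  expect_equal(project_genes(gv, sel), gv[, 1:2])
  expect_equal(project_genes(gv, matrix(0, 3, 2)), matrix(0, 4, 2))
  set.seed(2)
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(project_genes(gv, W), oracle_matmul(gv, W))
  expect_error(project_genes(gv, matrix(0, 2, 2)), "mismatch")
})

test_that("alpha = 0 and constant p both collapse S to the row-normalized prior", {
  set.seed(11)
  for (i in 1:5) {
    A <- toy_adjacency(paste0("G", 1:20), edge_prob = 0.3, seed = i)
    A_phi <- power_adjacency(A, 1.7)
    g <- matrix(rnorm(20 * 4), 20, 4)
    p <- runif(20)
    S0 <- compute_learned_graph(g, p, A_phi, alpha = rep(0, 4))
    expect_lt(max(abs(S0 - A_phi / rowSums(A_phi))), 1e-10)
    S1 <- compute_learned_graph(g, rep(0.42, 20), A_phi, alpha = rnorm(4))
    expect_lt(max(abs(S1 - A_phi / rowSums(A_phi))), 1e-10)
  }
})

test_that("learned graph matches per-entry hand computation on a 3-gene path", {
  # path graph 1-2-3 with self-loops, sigma = ReLU
  A <- matrix(c(1, 0.8, 0,
                0.8, 1, 0.9,
                0, 0.9, 1), 3, 3, byrow = TRUE)
  g <- matrix(c(1, 0,
                0, 1,
                2, -1), 3, 2, byrow = TRUE)
  p <- c(0.1, 0.5, 0.9)
  alpha <- c(1, -2)
  S <- compute_learned_graph(g, p, A, alpha, activation = "relu")
  e <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    u <- sum(alpha * ((p[i] - p[j]) * (g[i, ] - g[j, ])))
    e[i, j] <- exp(max(u, 0))
  }
  expected <- (A * e) / rowSums(A * e)
  expect_equal(S, expected, tolerance = 1e-12)
})

test_that("S is row-stochastic with support inside the prior for random draws", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    A <- toy_adjacency(paste0("G", seq_len(n)), edge_prob = runif(1, 0.1, 0.6),
                       seed = i + 1000)
    phi <- runif(1, 0.5, 4)
    A_phi <- power_adjacency(A, phi)
    d <- sample(2:6, 1)
    g <- matrix(rnorm(n * d, sd = 2), n, d)
    p <- runif(n)
    alpha <- rnorm(d, sd = 2)
    act <- sample(c("relu", "tanh", "identity"), 1)
    S <- compute_learned_graph(g, p, A_phi, alpha, activation = act)
    expect_lt(max(abs(rowSums(S) - 1)), 1e-5)
    expect_gte(min(S), 0)
    expect_identical(S == 0, A_phi == 0)
  }
})

test_that("a missing self-loop (all-zero row) is rejected", {
  A <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_error(compute_learned_graph(matrix(0, 2, 2), c(0, 1), A, c(0, 0)),
               "self-loop")
})

test_that("graph-learning loss matches the brute-force triple loop", {
  set.seed(55)
  A <- toy_adjacency(paste0("G", 1:3), edge_prob = 1, seed = 5)
  g <- matrix(rnorm(6), 3, 2)
  p <- c(0.2, 0.7, 0.4)
  S <- compute_learned_graph(g, p, A, rnorm(2))
  expect_equal(graph_learning_loss(S, g, p, A, 0.3, 0.7),
               oracle_graph_loss(S, g, p, A, 0.3, 0.7))

  for (i in 1:15) {
    n <- sample(3:10, 1); d <- sample(1:4, 1)
    A <- toy_adjacency(paste0("G", seq_len(n)), seed = i + 7)
    g <- matrix(rnorm(n * d), n, d)
    p <- runif(n)
    S <- compute_learned_graph(g, p, A, rnorm(d))
    gamma <- runif(1); beta <- runif(1)
    expect_equal(graph_learning_loss(S, g, p, A, gamma, beta),
                 oracle_graph_loss(S, g, p, A, gamma, beta), tolerance = 1e-12)
  }
})

test_that("loss term isolation and zero cases hold", {
  A <- toy_adjacency(paste0("G", 1:4), seed = 2)
  g <- matrix(rnorm(8), 4, 2)
  p_const <- rep(0.5, 4)
  S <- compute_learned_graph(g, p_const, A, rnorm(2))
  expect_equal(graph_learning_loss(S, g, p_const, A, 0, 0), 0)
  # S = A_phi, zero distances, gamma = 1, beta = 0 -> squared Frobenius norm
  g0 <- matrix(0, 4, 2)
  expect_equal(graph_learning_loss(A, g0, runif(4), A, 1, 0), sum(A^2))
})

test_that("loss is invariant to shifting all frequencies by a constant", {
  set.seed(6)
  A <- toy_adjacency(paste0("G", 1:6), seed = 13)
  g <- matrix(rnorm(18), 6, 3)
  p <- runif(6)
  alpha <- rnorm(3)
  for (shift in c(-2, 0.5, 10)) {
    S1 <- compute_learned_graph(g, p, A, alpha)
    S2 <- compute_learned_graph(g, p + shift, A, alpha)
    expect_equal(S2, S1, tolerance = 1e-12)
    expect_equal(graph_learning_loss(S2, g, p + shift, A, 0.1, 0.2),
                 graph_learning_loss(S1, g, p, A, 0.1, 0.2), tolerance = 1e-10)
  }
})

test_that("increasing gamma never decreases the loss", {
  A <- toy_adjacency(paste0("G", 1:5), seed = 21)
  g <- matrix(rnorm(10), 5, 2)
  p <- runif(5)
  S <- compute_learned_graph(g, p, A, rnorm(2))
  gammas <- c(0, 0.01, 0.1, 1, 10)
  losses <- vapply(gammas, function(gm) graph_learning_loss(S, g, p, A, gm, 0.3),
                   numeric(1))
  expect_true(all(diff(losses) >= 0))
})
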