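test_that("graph convolution has the identity and averaging closed forms", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_forward(X, diag(4), diag(3)), X)
  # row-normalized complete graph averages every node's features
  S <- matrix(1 / 4, 4, 4)
  W <- matrix(rnorm(6), 3, 2)
  out <- gcn_forward(X, S, W)
  expect_equal(out, matrix(rep(colMeans(X) %*% W, each = 4), 4, 2))
})

test_that("graph convolution matches explicit per-entry arithmetic", {
  S <- matrix(c(0.5, 0.5, 0, 0.2, 0.6, 0.2, 0, 0.3, 0.7), 3, 3, byrow = TRUE)
  X <- matrix(c(1, -1, 2, 0.5, 0, -2), 3, 2)
  W <- matrix(c(1, 0.5, -1, 2), 2, 2)
  out <- gcn_forward(X, S, W, activation = "relu")
  expected <- oracle_matmul(oracle_matmul(S, X), W)
  expected[expected < 0] <- 0
  expect_equal(out, expected)
  expect_error(gcn_forward(X, S, matrix(0, 3, 2)), "channel")
})

test_that("cross-entropy loss matches hand computation", {
  expect_equal(classification_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(classification_loss(0.5, 1), log(2))
  z <- c(0.8, 0.3); y <- c(1, 0)
  expect_equal(classification_loss(z, y), -(log(0.8) + log(0.7)) / 2)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    z <- runif(n); y <- rbinom(n, 1, 0.5)
    expect_equal(classification_loss(z, y), oracle_cross_entropy(z, y))
    expect_equal(classification_loss(z, y),
                 classification_loss(rev(z), rev(y)))  # permutation invariance
  }
})

test_that("total loss combines the terms linearly", {
  expect_equal(total_loss(2, 3, 0), 2)
  expect_equal(total_loss(0, 3, 0.5), 1.5)
  expect_equal(total_loss(2, 3, 0.5), 3.5)
  lams <- seq(0, 2, by = 0.25)
  vals <- vapply(lams, function(l) total_loss(1.5, 2.5, l), numeric(1))
  expect_equal(diff(vals), rep(2.5 * 0.25, length(lams) - 1))
})

test_that("forward pass yields probability rows on an untrained model", {
  cfg <- quick_config(seed = 42)
  A <- toy_adjacency(paste0("G", 1:12), seed = 3)
  model <- build_model(cfg, paste0("G", 1:12))
  model <- bioglgcn:::attach_prior(model, A, setNames(runif(12), paste0("G", 1:12)))
  X <- matrix(rnorm(10 * 12), 10, 12, dimnames = list(NULL, paste0("G", 1:12)))
  probs <- predict(model, X)
  expect_equal(dim(probs), c(10, 2))
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  N <- 7; M <- 6
  gene_ids <- paste0("G", 1:N)
  cfg <- model_config(hidden_dims_gcn = c(3, 2), hidden_dims_fc = c(5, 4, 2),
                      d = 3, activation = "tanh", graph_activation = "tanh",
                      batch_norm = TRUE, gamma = 0.05, beta = 0.2, lambda = 0.7,
                      phi = 2, batch_size = M, seed = 9)
  A <- toy_adjacency(gene_ids, edge_prob = 0.5, seed = 12)
  p <- setNames(runif(N), gene_ids)
  X <- matrix(rnorm(M * N), M, N, dimnames = list(paste0("S", 1:M), gene_ids))
  y <- rep(c(0, 1), 3)
  for (abl in c("none", "no_frequency", "fixed_graph")) {
    cfg$ablation <- abl
    model <- build_model(cfg, gene_ids)
    model <- bioglgcn:::attach_prior(model, A, p)
    model <- bioglgcn:::init_wg(model, M)
    set.seed(5)  # move off the alpha = 0 stationary point
    for (nm in names(model$params)) {
      pp <- model$params[[nm]]
      if (!is.null(pp)) model$params[[nm]] <- pp + rnorm(length(pp), sd = 0.2)
    }
    grads <- model_gradients(model, X, y)
    loss_at <- function(m) bioglgcn:::model_step(m, X, y, TRUE, FALSE)$L
    h <- 1e-6
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      for (i in seq_len(min(length(g), 5))) {
        mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
        mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        err <- abs(fd - g[i]) / max(1, abs(fd), abs(g[i]))
        expect_lt(err, 1e-5,
                  label = sprintf("%s gradient error of %s[%d]", abl, nm, i))
      }
    }
  }
})

test_that("fixed-graph ablation has exactly zero graph-parameter gradients", {
  cfg <- quick_config(ablation = "fixed_graph", seed = 7)
  gene_ids <- paste0("G", 1:10)
  A <- toy_adjacency(gene_ids, seed = 4)
  model <- build_model(cfg, gene_ids)
  model <- bioglgcn:::attach_prior(model, A, setNames(runif(10), gene_ids))
  X <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(NULL, gene_ids))
  grads <- model_gradients(model, X, rep(c(0, 1), 4))
  expect_true(all(grads$alpha == 0))
  expect_true(all(grads$W_g == 0))
  expect_true(any(grads$Wf1 != 0))  # the classifier itself does get gradient
})

test_that("frequency-free ablation equals the full model under constant p", {
  gene_ids <- paste0("G", 1:10)
  A <- toy_adjacency(gene_ids, seed = 8)
  p_const <- setNames(rep(0.5, 10), gene_ids)
  X <- matrix(rnorm(12 * 10), 12, 10, dimnames = list(NULL, gene_ids))
  m_full <- build_model(quick_config(ablation = "none", seed = 77), gene_ids)
  m_nofreq <- build_model(quick_config(ablation = "no_frequency", seed = 77), gene_ids)
  m_full <- bioglgcn:::attach_prior(m_full, A, p_const)
  m_nofreq <- bioglgcn:::attach_prior(m_nofreq, A, p_const)
  expect_identical(predict(m_full, X), predict(m_nofreq, X))
})

test_that("training is bit-deterministic given a seed", {
  gene_ids <- paste0("G", 1:8)
  A <- toy_adjacency(gene_ids, seed = 14)
  set.seed(1)
  X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(paste0("S", 1:40), gene_ids))
  y <- rbinom(40, 1, 0.5)
  freq <- setNames(runif(8), gene_ids)
  cfg <- quick_config(epochs = 5, batch_size = 20)
  f1 <- fit_biogl_gcn(X, y, A, freq, cfg, seed = 123)
  f2 <- fit_biogl_gcn(X, y, A, freq, cfg, seed = 123)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$S, f2$S)
  f3 <- fit_biogl_gcn(X, y, A, freq, cfg, seed = 124)
  expect_false(identical(f1$history, f3$history))
})
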