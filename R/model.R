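#' Model configuration
#'
#' Bundles every architecture and optimization hyperparameter of the
#' graph-learning classifier. The network stacks a BioGL graph-learning layer,
#' two graph convolutional layers, a flatten stage and three fully connected
#' layers with a softmax output; batch normalization follows the BioGL layer
#' and each graph convolutional layer.
#'
#' @param hidden_dims_gcn Widths of the two graph convolutional layers.
#' @param hidden_dims_fc Widths of the three fully connected layers; the last
#'   must equal `n_classes`.
#' @param n_classes Number of output classes (2: DILI positive / negative).
#' @param activation Nonlinearity for the convolutional and fully connected
#'   layers (`"relu"`, `"tanh"`, `"identity"`).
#' @param graph_activation Nonlinearity inside the graph-learning layer.
#' @param batch_norm Use batch normalization? Default `TRUE`.
#' @param d Projection dimension of the graph-learning layer.
#' @param phi Elementwise power applied to the adjacency prior.
#' @param gamma,beta Graph-learning loss weights (Frobenius and
#'   prior-anchoring terms).
#' @param lambda Mixing weight of the classification loss in the joint loss
#'   `L1 + lambda * L2`. The default (100) makes `lambda * L2` commensurate
#'   with `L1`, whose Frobenius terms grow with the square of the gene count;
#'   with a small `lambda` the classification objective would be numerically
#'   invisible to the graph-learning parameters.
#' @param ablation `"none"` for the full model; `"fixed_graph"` replaces the
#'   learned graph by the row-normalized prior (plain GCN baseline);
#'   `"no_frequency"` drops the gene-frequency factor from the learned graph
#'   (frequency-free graph-learning baseline).
#' @param lr,epochs,batch_size Adam learning rate, training epochs, and
#'   minibatch size (`NULL` = full batch). The graph is recomputed from each
#'   minibatch's cross-sample gene vectors, so the projection matrix has
#'   `batch_size` rows.
#' @param dropout Dropout rate on the fully connected hidden activations;
#'   off (0) by default.
#' @param seed Integer seed controlling initialization and minibatch order.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_dims_gcn = c(64, 32),
                         hidden_dims_fc = c(256, 64, 2),
                         n_classes = 2,
                         activation = "relu",
                         graph_activation = "tanh",
                         batch_norm = TRUE,
                         d = 32,
                         phi = 1,
                         gamma = 0.01,
                         beta = 0.1,
                         lambda = 100,
                         ablation = c("none", "fixed_graph", "no_frequency"),
                         lr = 1e-3,
                         epochs = 100,
                         batch_size = 64,
                         dropout = 0,
                         seed = 1L) {
  ablation <- match.arg(ablation)
  stopifnot(length(hidden_dims_gcn) == 2, all(hidden_dims_gcn >= 1),
            length(hidden_dims_fc) == 3, all(hidden_dims_fc >= 1),
            n_classes == 2, phi > 0, gamma >= 0, beta >= 0, lambda >= 0,
            d >= 1, lr > 0, epochs >= 1, dropout >= 0, dropout < 1)
  if (hidden_dims_fc[[3]] != n_classes) {
    stop_validation("the last fully connected width must equal n_classes")
  }
  activation_fun(activation)
  activation_fun(graph_activation)
  cfg <- list(
    hidden_dims_gcn = as.integer(hidden_dims_gcn),
    hidden_dims_fc = as.integer(hidden_dims_fc),
    n_classes = as.integer(n_classes),
    activation = activation,
    graph_activation = graph_activation,
    batch_norm = isTRUE(batch_norm),
    d = as.integer(d), phi = phi, gamma = gamma, beta = beta, lambda = lambda,
    ablation = ablation,
    lr = lr, epochs = as.integer(epochs),
    batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
    dropout = dropout,
    seed = as.integer(seed)
  )
  class(cfg) <- "model_config"
  cfg
}

glorot <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

#' Build an (untrained) graph-learning GCN model
#'
#' Initializes all trainable parameters from `config$seed`. The graph
#' projection matrix `W_g` is created lazily at first forward/training call,
#' when the number of samples forming the cross-sample gene vectors is known;
#' the graph-attention vector `alpha` starts at zero, so a freshly built
#' model's learned graph equals the row-normalized powered prior.
#'
#' @param config A [model_config()].
#' @param gene_ids Character vector of gene ids (or a single integer, the
#'   gene count, for anonymous genes).
#' @return A `biogl_gcn` model object (untrained).
#' @export
build_model <- function(config, gene_ids) {
  stopifnot(inherits(config, "model_config"))
  if (is.numeric(gene_ids) && length(gene_ids) == 1) {
    gene_ids <- paste0("G", seq_len(gene_ids))
  }
  N <- length(gene_ids)
  h <- config$hidden_dims_gcn
  f <- config$hidden_dims_fc
  n_flat <- N * h[[2]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  params <- list(
    W_g = NULL,  # K x d, created when K is known
    alpha = rep(0, config$d),
    w0 = rnorm(h[[1]], sd = sqrt(2 / (1 + h[[1]]))),
    W1 = glorot(h[[1]], h[[2]]),
    Wf1 = glorot(n_flat, f[[1]]), bf1 = rep(0, f[[1]]),
    Wf2 = glorot(f[[1]], f[[2]]), bf2 = rep(0, f[[2]]),
    Wf3 = glorot(f[[2]], f[[3]]), bf3 = rep(0, f[[3]])
  )
  if (config$batch_norm) {
    params$bn0_g <- 1; params$bn0_b <- 0
    params$bn1_g <- rep(1, h[[1]]); params$bn1_b <- rep(0, h[[1]])
    params$bn2_g <- rep(1, h[[2]]); params$bn2_b <- rep(0, h[[2]])
  }
  model <- list(
    config = config,
    gene_ids = toupper(gene_ids),
    params = params,
    bn_state = list(),   # running means/vars, filled during training
    S = NULL,            # frozen learned graph, set after fitting
    A = NULL, A_phi = NULL, S_fixed = NULL,
    freq_norm = NULL,
    history = NULL,
    trained = FALSE
  )
  class(model) <- "biogl_gcn"
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

init_wg <- function(model, K) {
  if (!is.null(model$params$W_g) && nrow(model$params$W_g) == K) return(model)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((model$config$seed + 104729L) %% .Machine$integer.max)
  model$params$W_g <- matrix(rnorm(K * model$config$d, sd = 1 / sqrt(K)),
                             K, model$config$d)
  model
}

# Attach the graph prior (with self-loops), its elementwise power, the
# row-normalized fixed graph, and the aligned frequency vector to the model.
attach_prior <- function(model, A, frequencies) {
  A <- A[model$gene_ids, model$gene_ids]
  A_self <- add_self_loops(A)
  model$A <- A_self
  model$A_phi <- power_adjacency(A_self, model$config$phi)
  model$S_fixed <- A_self / rowSums(A_self)
  if (model$config$ablation == "no_frequency") {
    model$freq_norm <- NULL
  } else {
    model$freq_norm <- align_frequencies(frequencies, model$gene_ids)
  }
  model
}

# ---- batch normalization ----------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_forward <- function(x, g, b, run = NULL, training = TRUE) {
  if (training || is.null(run)) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- run$mean
    v <- run$var
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(x, 2, mu, "-"), 2, istd, "*")
  out <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  new_run <- if (training) {
    if (is.null(run)) list(mean = mu, var = v)
    else list(mean = BN_MOMENTUM * run$mean + (1 - BN_MOMENTUM) * mu,
              var = BN_MOMENTUM * run$var + (1 - BN_MOMENTUM) * v)
  } else run
  list(out = out, xhat = xhat, istd = istd, run = new_run)
}

bn_backward <- function(dout, cache, g) {
  R <- nrow(dout)
  dg <- colSums(dout * cache$xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, m1, "-") - sweep(cache$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$istd, "*")
  list(dx = dx, dg = dg, db = db)
}

# ---- tensor helpers (arrays are samples x nodes x channels) -----------------

node_mix <- function(S, H) {
  d <- dim(H)
  Hp <- aperm(H, c(2, 1, 3))
  dim(Hp) <- c(d[[2]], d[[1]] * d[[3]])
  R <- S %*% Hp
  dim(R) <- c(d[[2]], d[[1]], d[[3]])
  aperm(R, c(2, 1, 3))
}

chan_mul <- function(H, W) {
  d <- dim(H)
  Hm <- H
  dim(Hm) <- c(d[[1]] * d[[2]], d[[3]])
  R <- Hm %*% W
  dim(R) <- c(d[[1]], d[[2]], ncol(W))
  R
}

# sum over samples and channels of dZ[m,i,k] * B[m,j,k]  ->  N x N
ds_accum <- function(dZ, B) {
  d <- dim(dZ)
  Dp <- aperm(dZ, c(2, 1, 3)); dim(Dp) <- c(d[[2]], d[[1]] * d[[3]])
  Bp <- aperm(B, c(2, 1, 3));  dim(Bp) <- c(d[[2]], d[[1]] * d[[3]])
  tcrossprod(Dp, Bp)
}

# ---- learned-graph forward/backward -----------------------------------------

graph_forward <- function(params, X, p, A_phi, config) {
  Gt <- t(X)                                    # N x K gene vectors
  g_tilde <- Gt %*% params$W_g
  q <- as.numeric(g_tilde %*% params$alpha)
  Dq <- outer(q, q, "-")
  Dp <- if (is.null(p)) NULL else outer(p, p, "-")
  u <- if (is.null(Dp)) Dq else Dp * Dq
  sigma <- activation_fun(config$graph_activation)
  f_raw <- sigma(u)
  f <- pmin(pmax(f_raw, -EXP_CLIP), EXP_CLIP)
  E <- A_phi * exp(f)
  rs <- rowSums(E)
  S <- E / rs
  list(S = S, g_tilde = g_tilde, q = q, u = u, f_raw = f_raw, Dp = Dp, Gt = Gt)
}

# Gradients of (classifier loss dS) + L1 with respect to W_g and alpha, plus
# the value of L1 itself.
graph_backward <- function(dS_cls, gf, params, A_phi, config) {
  S <- gf$S
  Dp2 <- if (is.null(gf$Dp)) NULL else gf$Dp^2
  sq <- rowSums(gf$g_tilde^2)
  G2 <- outer(sq, sq, "+") - 2 * tcrossprod(gf$g_tilde)
  G2[G2 < 0] <- 0
  Dsq <- if (is.null(Dp2)) G2 else Dp2 * G2
  L1 <- sum(Dsq * S) + config$gamma * sum(S^2) + config$beta * sum((S - A_phi)^2)

  dS <- dS_cls + Dsq + 2 * config$gamma * S + 2 * config$beta * (S - A_phi)

  # distance term's direct dependence on g_tilde (graph-Laplacian form)
  Wp <- (S + t(S)) * (if (is.null(Dp2)) 1 else Dp2)
  dg_tilde <- 2 * (rowSums(Wp) * gf$g_tilde - Wp %*% gf$g_tilde)

  # through the row-softmax: dL/df_ij = S_ij (dS_ij - sum_k dS_ik S_ik)
  rowdot <- rowSums(dS * S)
  dF <- S * sweep(dS, 1, rowdot, "-")
  clip_mask <- (abs(gf$f_raw) < EXP_CLIP) * 1
  du <- dF * clip_mask * activation_grad(config$graph_activation)(gf$u)
  Tm <- if (is.null(gf$Dp)) du else du * gf$Dp
  dq <- rowSums(Tm) - colSums(Tm)
  dalpha <- as.numeric(crossprod(gf$g_tilde, dq))
  dg_tilde <- dg_tilde + outer(dq, params$alpha)
  dW_g <- crossprod(gf$Gt, dg_tilde)  # t(Gt) %*% dg_tilde: (K x N) %*% (N x d)
  list(L1 = L1, dW_g = dW_g, dalpha = dalpha)
}

# ---- classifier forward/backward --------------------------------------------

cls_forward <- function(params, bn_state, X, S, config, training = TRUE,
                        dropout_masks = NULL) {
  M <- nrow(X); N <- ncol(X)
  act <- activation_fun(config$activation)
  cache <- list(M = M, N = N)
  new_bn <- bn_state

  if (config$batch_norm) {
    b0 <- bn_forward(matrix(as.numeric(X), ncol = 1), params$bn0_g, params$bn0_b,
                     bn_state$bn0, training)
    new_bn$bn0 <- b0$run
    X0b <- matrix(b0$out, M, N)
    cache$b0 <- b0
  } else {
    X0b <- X
  }
  cache$X0b <- X0b

  tP1 <- X0b %*% t(S)
  Z1 <- outer(tP1, params$w0)                   # M x N x h0
  if (config$batch_norm) {
    h0 <- dim(Z1)[[3]]
    Z1m <- Z1; dim(Z1m) <- c(M * N, h0)
    b1 <- bn_forward(Z1m, params$bn1_g, params$bn1_b, bn_state$bn1, training)
    new_bn$bn1 <- b1$run
    Z1a <- b1$out; dim(Z1a) <- c(M, N, h0)
    cache$b1 <- b1
  } else {
    Z1a <- Z1
  }
  H1 <- act(Z1a)
  cache$tP1 <- tP1; cache$Z1a <- Z1a; cache$H1 <- H1

  B2 <- chan_mul(H1, params$W1)
  Z2 <- node_mix(S, B2)
  if (config$batch_norm) {
    h1 <- dim(Z2)[[3]]
    Z2m <- Z2; dim(Z2m) <- c(M * N, h1)
    b2 <- bn_forward(Z2m, params$bn2_g, params$bn2_b, bn_state$bn2, training)
    new_bn$bn2 <- b2$run
    Z2a <- b2$out; dim(Z2a) <- c(M, N, h1)
    cache$b2 <- b2
  } else {
    Z2a <- Z2
  }
  H2 <- act(Z2a)
  cache$B2 <- B2; cache$Z2a <- Z2a; cache$H2 <- H2

  Fm <- H2; dim(Fm) <- c(M, N * dim(H2)[[3]])
  ZA1 <- sweep(Fm %*% params$Wf1, 2, params$bf1, "+")
  A1 <- act(ZA1)
  if (training && config$dropout > 0) {
    m1 <- dropout_masks$m1 %||% (matrix(runif(length(A1)) >= config$dropout,
                                        nrow(A1)) / (1 - config$dropout))
    A1 <- A1 * m1
    cache$drop1 <- m1
  }
  ZA2 <- sweep(A1 %*% params$Wf2, 2, params$bf2, "+")
  A2 <- act(ZA2)
  if (training && config$dropout > 0) {
    m2 <- dropout_masks$m2 %||% (matrix(runif(length(A2)) >= config$dropout,
                                        nrow(A2)) / (1 - config$dropout))
    A2 <- A2 * m2
    cache$drop2 <- m2
  }
  logits <- sweep(A2 %*% params$Wf3, 2, params$bf3, "+")
  lmax <- apply(logits, 1, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  cache$Fm <- Fm; cache$ZA1 <- ZA1; cache$A1 <- A1
  cache$ZA2 <- ZA2; cache$A2 <- A2
  list(probs = probs, cache = cache, bn_state = new_bn)
}

cls_backward <- function(dlogits, cache, params, S, config) {
  actg <- activation_grad(config$activation)
  g <- list()
  g$Wf3 <- crossprod(cache$A2, dlogits)
  g$bf3 <- colSums(dlogits)
  dA2 <- dlogits %*% t(params$Wf3)
  if (!is.null(cache$drop2)) dA2 <- dA2 * cache$drop2
  dZA2 <- dA2 * actg(cache$ZA2)
  g$Wf2 <- crossprod(cache$A1, dZA2)
  g$bf2 <- colSums(dZA2)
  dA1 <- dZA2 %*% t(params$Wf2)
  if (!is.null(cache$drop1)) dA1 <- dA1 * cache$drop1
  dZA1 <- dA1 * actg(cache$ZA1)
  g$Wf1 <- crossprod(cache$Fm, dZA1)
  g$bf1 <- colSums(dZA1)
  dFm <- dZA1 %*% t(params$Wf1)

  M <- cache$M; N <- cache$N
  h1 <- dim(cache$H2)[[3]]
  dH2 <- dFm; dim(dH2) <- c(M, N, h1)
  dZ2a <- dH2 * actg(cache$Z2a)
  if (config$batch_norm) {
    dZ2m <- dZ2a; dim(dZ2m) <- c(M * N, h1)
    bb2 <- bn_backward(dZ2m, cache$b2, params$bn2_g)
    g$bn2_g <- bb2$dg; g$bn2_b <- bb2$db
    dZ2 <- bb2$dx; dim(dZ2) <- c(M, N, h1)
  } else {
    dZ2 <- dZ2a
  }
  dS <- ds_accum(dZ2, cache$B2)
  dB2 <- node_mix(t(S), dZ2)
  h0 <- dim(cache$H1)[[3]]
  H1m <- cache$H1; dim(H1m) <- c(M * N, h0)
  dB2m <- dB2; dim(dB2m) <- c(M * N, h1)
  g$W1 <- crossprod(H1m, dB2m)
  dH1m <- dB2m %*% t(params$W1)
  dH1 <- dH1m; dim(dH1) <- c(M, N, h0)

  dZ1a <- dH1 * actg(cache$Z1a)
  if (config$batch_norm) {
    dZ1m <- dZ1a; dim(dZ1m) <- c(M * N, h0)
    bb1 <- bn_backward(dZ1m, cache$b1, params$bn1_g)
    g$bn1_g <- bb1$dg; g$bn1_b <- bb1$db
    dZ1 <- bb1$dx; dim(dZ1) <- c(M, N, h0)
  } else {
    dZ1 <- dZ1a
  }
  # Z1[m,n,k] = tP1[m,n] * w0[k]
  dZ1m2 <- dZ1; dim(dZ1m2) <- c(M * N, h0)
  g$w0 <- as.numeric(crossprod(dZ1m2, as.numeric(cache$tP1)))
  dtP1 <- matrix(dZ1m2 %*% params$w0, M, N)
  # tP1 = X0b %*% t(S)
  dS <- dS + crossprod(dtP1, cache$X0b)
  if (config$batch_norm) {
    dX0b <- dtP1 %*% S
    bb0 <- bn_backward(matrix(as.numeric(dX0b), ncol = 1), cache$b0, params$bn0_g)
    g$bn0_g <- bb0$dg; g$bn0_b <- bb0$db
  }
  list(grads = g, dS = dS)
}

# ---- losses -----------------------------------------------------------------

#' Graph convolution of node features
#'
#' One graph convolutional layer applied to a single sample's node features:
#' `sigma(S X W)` — propagate over the graph, transform channels, then apply
#' the nonlinearity.
#'
#' @param X N x h_in node-feature matrix (a length-N vector is treated as
#'   N x 1).
#' @param S N x N (learned) graph.
#' @param W h_in x h_out layer weight matrix.
#' @param activation Name of the nonlinearity (default `"identity"`).
#' @return N x h_out matrix of next-layer node features.
#' @export
gcn_forward <- function(X, S, W, activation = "identity") {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(W)) W <- matrix(W, nrow = ncol(X))
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (nrow(X) != nrow(S)) stop_validation("X must have one row per graph node")
  if (ncol(X) != nrow(W)) stop_validation("W must have one row per input channel")
  activation_fun(activation)(S %*% X %*% W)
}

#' Binary cross-entropy classification loss
#'
#' `-(1/n) sum(y log z + (1-y) log(1-z))` in natural log, with predicted
#' positive-class probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param z Predicted positive-class probabilities.
#' @param y Binary labels (0/1).
#' @return Nonnegative scalar.
#' @export
classification_loss <- function(z, y) {
  stopifnot(length(z) == length(y), all(y %in% c(0, 1)))
  z <- pmin(pmax(z, 1e-7), 1 - 1e-7)
  -mean(y * log(z) + (1 - y) * log(1 - z))
}

#' Joint loss of the graph-learning classifier
#'
#' @param L1 Graph-learning loss ([graph_learning_loss()]).
#' @param L2 Classification loss ([classification_loss()]).
#' @param lambda Nonnegative mixing weight.
#' @return `L1 + lambda * L2`.
#' @export
total_loss <- function(L1, L2, lambda) {
  L1 + lambda * L2
}

# L1 with p = NULL meaning the frequency-free ablation (unit frequency factor)
l1_value <- function(S, g_tilde, p, A_phi, config) {
  sum(pairwise_weighted_dist2(g_tilde, p) * S) +
    config$gamma * sum(S^2) + config$beta * sum((S - A_phi)^2)
}

# ---- one training/evaluation step -------------------------------------------

# Forward pass + losses (+ gradients when `backward`) on one batch.
model_step <- function(model, X, y, training = TRUE, backward = TRUE) {
  config <- model$config
  fixed <- config$ablation == "fixed_graph"
  if (fixed) {
    S <- model$S_fixed
    gf <- NULL
  } else {
    gf <- graph_forward(model$params, X, model$freq_norm, model$A_phi, config)
    S <- gf$S
  }
  fw <- cls_forward(model$params, model$bn_state, X, S, config, training)
  z <- fw$probs[, 2]
  L2 <- classification_loss(z, y)
  if (!backward) {
    L1 <- if (fixed) 0 else l1_value(S, gf$g_tilde, model$freq_norm, model$A_phi, config)
    return(list(probs = fw$probs, L1 = L1, L2 = L2,
                L = total_loss(L1, L2, config$lambda),
                S = S, bn_state = fw$bn_state))
  }
  Y1 <- cbind(1 - y, y)
  dlogits <- config$lambda * (fw$probs - Y1) / nrow(X)
  cb <- cls_backward(dlogits, fw$cache, model$params, S, config)
  grads <- cb$grads
  if (fixed) {
    L1 <- 0
    grads$W_g <- if (is.null(model$params$W_g)) NULL else 0 * model$params$W_g
    grads$alpha <- 0 * model$params$alpha
  } else {
    gb <- graph_backward(cb$dS, gf, model$params, model$A_phi, config)
    L1 <- gb$L1
    grads$W_g <- gb$dW_g
    grads$alpha <- gb$dalpha
  }
  list(probs = fw$probs, L1 = L1, L2 = L2,
       L = total_loss(L1, L2, config$lambda),
       S = S, bn_state = fw$bn_state, grads = grads)
}

#' Parameter gradients of the joint loss on one batch
#'
#' Computes the analytic gradients of `L1 + lambda * L2` with respect to every
#' trainable parameter for a given batch. Mostly useful for testing and
#' diagnostics; under the `fixed_graph` ablation the gradients with respect to
#' the graph-learning parameters `alpha` and `W_g` are exactly zero.
#'
#' @param model A `biogl_gcn` model with an attached prior (see
#'   [fit_biogl_gcn()]; untrained models are accepted).
#' @param X Samples-by-genes batch matrix, columns aligned to
#'   `model$gene_ids`.
#' @param y Binary labels.
#' @return Named list of gradient arrays.
#' @export
model_gradients <- function(model, X, y) {
  stopifnot(inherits(model, "biogl_gcn"))
  if (is.null(model$A_phi)) stop_validation("model has no attached graph prior")
  model <- init_wg(model, nrow(X))
  st <- model_step(model, X, y, training = TRUE, backward = TRUE)
  st$grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) if (is.null(p)) NULL else 0 * p),
       v = lapply(params, function(p) if (is.null(p)) NULL else 0 * p),
       t = 0)
}

adam_update <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr) || is.null(params[[nm]])) next
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- 0 * gr; state$v[[nm]] <- 0 * gr }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the graph-learning GCN classifier
#'
#' Trains the full stack (graph-learning layer, two graph convolutional
#' layers, three fully connected layers, softmax) with Adam on the joint loss
#' `L1 + lambda * L2`. The learned graph is recomputed from each minibatch's
#' cross-sample gene vectors during training; after training, a final graph
#' is frozen from the first `batch_size` training samples (the full set when
#' training full-batch) and used for all subsequent prediction.
#'
#' @param X Samples-by-genes expression matrix with dimnames.
#' @param y Binary labels (0/1), one per row of `X`.
#' @param A Symmetric gene-gene adjacency prior over (a superset of) the
#'   columns of `X`; self-loops are inserted automatically.
#' @param frequencies Gene-frequency tibble from [gene_frequencies()] (or a
#'   named numeric vector of normalized frequencies).
#' @param config A [model_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param verbose Print a progress line every 20 epochs?
#' @return A trained `biogl_gcn` object with elements `S` (frozen learned
#'   graph), `history` (per-epoch loss tibble) and the trained parameters.
#' @export
fit_biogl_gcn <- function(X, y, A, frequencies, config = model_config(),
                          seed = config$seed, verbose = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0, 1)))
  validate_expression(X)
  colnames(X) <- toupper(colnames(X))
  missing <- setdiff(colnames(X), rownames(A))
  if (length(missing) > 0) {
    stop_validation(paste0("gene(s) absent from adjacency prior: ",
                           paste(head(missing, 10), collapse = ", ")))
  }
  config$seed <- as.integer(seed)
  model <- build_model(config, colnames(X))
  model <- attach_prior(model, A, frequencies)
  X <- X[, model$gene_ids, drop = FALSE]

  n <- nrow(X)
  K <- min(config$batch_size %||% n, n)
  model <- init_wg(model, K)
  adam <- adam_init(model$params)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((config$seed + 211L) %% .Machine$integer.max)

  n_batches <- max(1L, floor(n / K))
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    l1s <- l2s <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1) * K + 1):(b * K)]
      st <- model_step(model, X[idx, , drop = FALSE], y[idx],
                       training = TRUE, backward = TRUE)
      model$bn_state <- st$bn_state
      upd <- adam_update(model$params, st$grads, adam, config$lr)
      model$params <- upd$params
      adam <- upd$state
      l1s[[b]] <- st$L1; l2s[[b]] <- st$L2
    }
    hist[[epoch]] <- c(L1 = mean(l1s), L2 = mean(l2s))
    if (verbose && epoch %% 20 == 0) {
      inform(sprintf("epoch %3d  L1 %.4f  L2 %.4f", epoch, mean(l1s), mean(l2s)))
    }
  }
  hm <- do.call(rbind, hist)
  model$history <- tibble(
    epoch = seq_len(config$epochs),
    L1 = hm[, "L1"], L2 = hm[, "L2"],
    total = hm[, "L1"] + config$lambda * hm[, "L2"]
  )

  # freeze the learned graph from a canonical training subset
  if (config$ablation == "fixed_graph") {
    model$S <- model$S_fixed
  } else {
    gf <- graph_forward(model$params, X[seq_len(K), , drop = FALSE],
                        model$freq_norm, model$A_phi, config)
    model$S <- gf$S
  }
  model$n_train <- n
  model$trained <- TRUE
  model
}

#' @export
print.biogl_gcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<biogl_gcn> %s model, %d genes%s\n",
              cfg$ablation, length(x$gene_ids),
              if (x$trained) sprintf(", trained %d epochs on %d samples",
                                     cfg$epochs, x$n_train) else " (untrained)"))
  if (x$trained) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: L1 %.4f, L2 %.4f, total %.4f\n",
                last$L1, last$L2, last$total))
  }
  invisible(x)
}

# Forward pass in evaluation mode; returns M x 2 class probabilities.
predict_probs <- function(model, X) {
  stopifnot(inherits(model, "biogl_gcn"))
  missing <- setdiff(model$gene_ids, toupper(colnames(X)))
  if (length(missing) > 0) {
    stop_validation(paste0("input is missing model gene(s): ",
                           paste(head(missing, 20), collapse = ", ")))
  }
  colnames(X) <- toupper(colnames(X))
  X <- X[, model$gene_ids, drop = FALSE]
  S <- model$S
  if (is.null(S)) {
    # untrained model: compute the graph from this batch
    if (model$config$ablation == "fixed_graph") {
      S <- model$S_fixed
    } else {
      model <- init_wg(model, nrow(X))
      S <- graph_forward(model$params, X, model$freq_norm, model$A_phi, model$config)$S
    }
  }
  fw <- cls_forward(model$params, model$bn_state, X, S, model$config,
                    training = FALSE)
  out <- fw$probs
  rownames(out) <- rownames(X)
  colnames(out) <- c("negative", "positive")
  out
}

#' @export
predict.biogl_gcn <- function(object, newdata, type = c("prob", "score"), ...) {
  type <- match.arg(type)
  probs <- predict_probs(object, newdata)
  if (type == "prob") probs else probs[, "positive"]
}
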