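small_spec <- function(...) {
  synthetic_spec(n_genes = 30, n_samples = 150, n_drugs = 10,
                 n_informative_genes = 6, n_terms = 25, ...)
}

test_that("generation is bit-deterministic in the seed", {
  d1 <- generate_dataset(small_spec(seed = 7))
  d2 <- generate_dataset(small_spec(seed = 7))
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$adjacency, d2$adjacency)
  expect_identical(unclass(d1$gene_sets), unclass(d2$gene_sets))
  d3 <- generate_dataset(small_spec(seed = 8))
  expect_false(identical(d1$expression, d3$expression))
})

test_that("generated adjacency satisfies the prior's invariants", {
  for (gm in c("erdos_renyi", "scale_free")) {
    ds <- generate_dataset(small_spec(graph_model = gm, seed = 3))
    A <- ds$adjacency
    expect_equal(A, t(A))
    expect_equal(diag(A), rep(1, nrow(A)), ignore_attr = TRUE)
    off <- A[upper.tri(A)]
    expect_true(all(off[off != 0] >= 0.7))
  }
})

test_that("informative genes form a connected subgraph", {
  ds <- generate_dataset(small_spec(seed = 5))
  idx <- match(ds$truth$informative, colnames(ds$expression))
  sub <- ds$adjacency[idx, idx]
  diag(sub) <- 0
  g <- igraph::graph_from_adjacency_matrix((sub > 0) * 1, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1)
})

test_that("an infeasible informative set is rejected", {
  spec <- synthetic_spec(n_genes = 40, n_samples = 50, n_drugs = 5,
                         edge_prob = 0.02, n_informative_genes = 35, seed = 1)
  expect_error(generate_dataset(spec), "component")
})

test_that("label prevalence matches the logistic model's implied prevalence", {
  for (s in 1:3) {
    ds <- generate_dataset(synthetic_spec(seed = s))
    p <- ds$truth$prob
    implied <- mean(p)
    se <- sqrt(sum(p * (1 - p))) / length(p)
    expect_lt(abs(mean(ds$labels$label) - implied), 3 * se + 1e-12)
  }
})

test_that("null effect gives chance-level oracle AUC and no expression-label link", {
  ds <- generate_dataset(small_spec(effect_size = 0, seed = 9))
  expect_true(all(ds$truth$prob == 0.5))
  # labels are coin flips: the best single-gene AUC stays near 0.5
  aucs <- apply(ds$expression, 2, function(g)
    compute_metrics(ds$labels$label, plogis(g))$auc)
  expect_lt(max(abs(aucs - 0.5)), 0.2)
})

test_that("planted frequencies are recovered by the enrichment pipeline", {
  ds <- generate_dataset(generate_spec <- synthetic_spec(seed = 21))
  freq <- gene_frequencies(ds$expression, ds$gene_sets)
  boost <- ds$truth$membership_rate[freq$gene_id]
  expect_gt(cor(freq$raw, boost, method = "spearman"), 0.5)
  # informative genes sit at the top of the normalized frequencies
  inf <- freq$gene_id %in% ds$truth$informative
  expect_gt(mean(freq$normalized[inf]), mean(freq$normalized[!inf]))
})

test_that("replicate sets reproduce the truth in the noise-free limit", {
  spec <- small_spec(noise_sd = 0, seed = 2)
  rs <- generate_replicate_set(spec)
  for (r in seq_len(nrow(rs$profiles))) {
    expect_equal(rs$profiles[r, ], rs$truth, ignore_attr = TRUE)
  }
})

test_that("an injected outlier is down-weighted and MODZ beats the mean", {
  down <- 0; modz_better <- 0; trials <- 60
  for (s in seq_len(trials)) {
    rs <- generate_replicate_set(small_spec(seed = 3000 + s), outlier = TRUE)
    cs <- modz_consensus(rs$profiles)
    R <- nrow(rs$profiles)
    if (cs$weights[R] < 1 / R) down <- down + 1
    plain <- colMeans(rs$profiles)
    if (cor(cs$values, rs$truth, method = "spearman") >=
        cor(plain, rs$truth, method = "spearman")) modz_better <- modz_better + 1
  }
  expect_gt(down / trials, 0.9)
  expect_gt(modz_better / trials, 0.6)
})

test_that("fixture bundles round-trip through the file formats", {
  ds <- generate_dataset(small_spec(seed = 13))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  mat <- suppressMessages(read_expression(file.path(dir, "expression.tsv")))
  expect_equal(mat, ds$expression)
  labels <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(labels, ds$labels)
  sets <- suppressMessages(read_gmt(file.path(dir, "gene_sets.gmt")))
  expect_equal(unclass(sets)[names(ds$gene_sets)], unclass(ds$gene_sets),
               ignore_attr = TRUE)
})
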