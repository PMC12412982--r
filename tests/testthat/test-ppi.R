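test_that("build_adjacency places scores symmetrically and drops unknown genes", {
  edges <- tibble::tibble(gene_a = "G1", gene_b = "G2", score = 0.9)
  A <- build_adjacency(edges, c("G1", "G2", "G3"))
  expect_equal(A["G1", "G2"], 0.9)
  expect_equal(A["G2", "G1"], 0.9)
  expect_equal(sum(A != 0), 2)

  A0 <- build_adjacency(edges[0, ], c("G1", "G2"))
  expect_true(all(A0 == 0))

  edges2 <- tibble::tibble(gene_a = c("G1", "G1"), gene_b = c("GX", "G2"),
                           score = c(0.8, 0.75))
  expect_message(A2 <- build_adjacency(edges2, c("G1", "G2")), "dropped 1")
  expect_equal(A2["G1", "G2"], 0.75)

  expect_error(build_adjacency(edges, character(0)), "nonempty")
})

test_that("build_adjacency is permutation-equivariant", {
  set.seed(7)
  genes <- paste0("G", 1:8)
  edges <- tibble::tibble(
    gene_a = c("G1", "G2", "G3", "G5"),
    gene_b = c("G4", "G6", "G7", "G8"),
    score = runif(4, 0.7, 1)
  )
  A <- build_adjacency(edges, genes)
  for (i in 1:5) {
    perm <- sample(genes)
    Ap <- build_adjacency(edges, perm)
    expect_equal(Ap, A[perm, perm])
  }
})

test_that("self-loop insertion sets the diagonal to 1 and is idempotent", {
  A <- matrix(0, 3, 3)
  expect_equal(add_self_loops(A), diag(3))
  A2 <- matrix(c(0.4, 0.8, 0.8, 0), 2, 2)
  out <- add_self_loops(A2)
  expect_equal(diag(out), c(1, 1))
  expect_equal(out[1, 2], 0.8)
  expect_equal(add_self_loops(out), out)
})

test_that("elementwise power preserves support, symmetry and fixed points", {
  expect_equal(power_adjacency(matrix(0.5, 1, 1), 2), matrix(0.25, 1, 1))
  A <- toy_adjacency(paste0("G", 1:6), seed = 3)
  expect_identical(power_adjacency(A, 1), A)
  for (phi in c(0.5, 2, 5)) {
    Ap <- power_adjacency(A, phi)
    expect_equal(Ap, t(Ap))
    expect_identical(Ap == 0, A == 0)
    expect_equal(diag(Ap), rep(1, 6), ignore_attr = TRUE)
  }
  # larger powers magnify the contrast between strong and weak edges
  vals <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(vals^2 < vals^1))
  expect_true(all(power_adjacency(matrix(vals, 1), 3) <
                  power_adjacency(matrix(vals, 1), 2)))
  expect_error(power_adjacency(A, 0), "positive")
})

test_that("graph_stats matches closed forms on canonical graphs", {
  complete4 <- matrix(1, 4, 4); diag(complete4) <- 0
  st <- graph_stats(complete4, edge_threshold = 0.5)
  expect_equal(st$clustering_coefficient, 1)
  expect_equal(st$density, 1)

  star4 <- matrix(0, 4, 4)
  star4[1, 2:4] <- star4[2:4, 1] <- 1
  st <- graph_stats(star4, edge_threshold = 0.5)
  expect_equal(st$clustering_coefficient, 0)
  expect_equal(st$density, 0.5)
})

test_that("clustering coefficient agrees with exhaustive triangle counting", {
  # 5-node graph: triangle 1-2-3 plus pendant edges 3-4 and 4-5
  A <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5))) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  st <- graph_stats(A, edge_threshold = 0.5)
  expect_equal(st$clustering_coefficient, oracle_transitivity(A))
  expect_equal(st$density, 5 / choose(5, 2))

  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    R <- matrix(runif(n * n), n, n)
    S <- (R + t(R)) / 2
    st <- graph_stats(S)
    bin <- (S + t(S)) / 2; diag(bin) <- 0
    bin <- (bin >= st$edge_threshold & bin > 0) * 1
    expect_equal(st$clustering_coefficient, oracle_transitivity(bin))
    expect_gte(st$density, 0); expect_lte(st$density, 1)
    expect_gte(st$clustering_coefficient, 0)
    expect_lte(st$clustering_coefficient, 1)
  }
})

test_that("adjacency export and import round-trip", {
  A <- toy_adjacency(paste0("G", 1:5), seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_matrix(A, path)
  expect_equal(read_adjacency_matrix(path), A)
  edges <- write_edge_list(A)
  expect_true(all(edges$weight >= 0.7))
  expect_true(all(edges$gene_a < edges$gene_b))
})
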