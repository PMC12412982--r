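#' Specification of a synthetic toxicogenomics benchmark
#'
#' Describes a fully synthetic stand-in for the training inputs of the
#' pipeline: a weighted gene-gene interaction graph, z-score-like expression
#' profiles grouped into drugs, binary toxicity labels driven by the
#' neighborhood-averaged expression of a planted connected set of informative
#' genes, gene sets in which informative genes are over-represented, and
#' replicate tables for the consensus-signature path.
#'
#' The defaults describe the benchmark used throughout the package's own
#' evaluation: 60 genes, 600 profiles from 30 drugs, 10 informative genes,
#' unit-variance background noise, and an effect size / label slope at which
#' an oracle using the true per-sample toxicity probabilities attains an AUC
#' of about 0.95.
#'
#' @param n_genes,n_samples,n_drugs Problem dimensions.
#' @param graph_model `"erdos_renyi"` (with `edge_prob`) or `"scale_free"`
#'   (preferential attachment with `attachment_power`).
#' @param edge_prob Edge probability of the Erdos-Renyi prior.
#' @param attachment_power Preferential-attachment exponent.
#' @param n_informative_genes Size of the planted connected informative set.
#' @param effect_size Expression shift per unit of a drug's latent toxicity
#'   on informative genes.
#' @param noise_sd Standard deviation of the expression background.
#' @param frequency_boost Multiplier on informative genes' gene-set
#'   membership rate (planted frequency signal).
#' @param n_terms Number of gene sets to emit.
#' @param term_rate Baseline gene-set membership probability per gene.
#' @param label_slope Slope of the logistic link from neighborhood-averaged
#'   planted signal to label probability.
#' @param replicates_per_compound Replicates per compound for
#'   [generate_replicate_set()].
#' @param seed Integer seed; everything is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 60, n_samples = 600, n_drugs = 30,
                           graph_model = c("erdos_renyi", "scale_free"),
                           edge_prob = 0.15, attachment_power = 1,
                           n_informative_genes = 10, effect_size = 1.5,
                           noise_sd = 1, frequency_boost = 4,
                           n_terms = 50, term_rate = 0.1,
                           label_slope = 8,
                           replicates_per_compound = 3, seed = 1L) {
  graph_model <- match.arg(graph_model)
  stopifnot(n_genes >= 2, n_samples >= 2, n_drugs >= 1,
            n_informative_genes >= 1, n_informative_genes <= n_genes,
            edge_prob > 0, edge_prob <= 1, effect_size >= 0, noise_sd >= 0,
            frequency_boost >= 1, n_terms >= 1, term_rate > 0,
            term_rate * frequency_boost <= 1, replicates_per_compound >= 1)
  spec <- as.list(environment())
  spec$seed <- as.integer(seed)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a complete synthetic dataset
#'
#' Produces every input the pipeline needs, with planted structure:
#'
#' * a symmetric adjacency prior with unit diagonal and STRING-like edge
#'   confidences in \[0.7, 1);
#' * a connected set of informative genes within that graph;
#' * per-drug latent toxicity `u_j ~ N(0,1)`; profiles are background noise
#'   plus `effect_size * u_j` on informative genes;
#' * per-sample label probability `plogis(label_slope * eta_j)` where
#'   `eta_j` is the noise-free neighborhood-averaged informative signal, so
#'   graph-aware classifiers have an advantage by construction and
#'   `effect_size = 0` makes labels pure coin flips;
#' * gene sets in which informative genes are `frequency_boost` times more
#'   likely to appear.
#'
#' @param spec A [synthetic_spec()].
#' @return A `biogl_dataset`: list with `expression` (samples x genes
#'   matrix), `labels` (tibble: `sample_id`, `label`, `group_id`),
#'   `adjacency`, `gene_sets`, `truth` (informative set, latent toxicities,
#'   per-sample probabilities, planted membership rates) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("G%03d", seq_len(n))

  g <- if (spec$graph_model == "erdos_renyi") {
    igraph::sample_gnp(n, spec$edge_prob)
  } else {
    igraph::sample_pa(n, power = spec$attachment_power, directed = FALSE)
  }
  A <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    w <- runif(nrow(el), 0.7, 0.999)
    A[el] <- w
    A[el[, c(2, 1), drop = FALSE]] <- w
  }
  A <- add_self_loops(A)

  # planted informative genes: a connected subgraph found by breadth-first
  # search inside the largest component
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  if (comp$csize[[big]] < spec$n_informative_genes) {
    stop_validation(sprintf(
      "largest graph component (%d nodes) is smaller than n_informative_genes (%d)",
      comp$csize[[big]], spec$n_informative_genes))
  }
  start <- which(comp$membership == big)[[1]]
  bfs_order <- igraph::bfs(g, root = start, order = TRUE)$order
  informative <- sort(as.integer(bfs_order[seq_len(spec$n_informative_genes)]))

  # per-drug latent toxicity and sample assignment (round-robin)
  drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
  u <- rnorm(spec$n_drugs)
  drug_of <- rep_len(seq_len(spec$n_drugs), spec$n_samples)
  M <- spec$n_samples

  X <- matrix(rnorm(M * n, sd = spec$noise_sd), M, n,
              dimnames = list(sprintf("S%04d", seq_len(M)), gene_ids))
  X[, informative] <- X[, informative] + spec$effect_size * u[drug_of]

  # noise-free neighborhood-averaged informative signal (closed neighborhood)
  supp <- (A != 0) * 1
  mu_ind <- numeric(n); mu_ind[informative] <- 1
  nb_frac <- (supp %*% mu_ind) / rowSums(supp)
  kappa <- mean(nb_frac[informative])
  eta <- spec$effect_size * u * kappa
  prob_drug <- plogis(spec$label_slope * eta)
  prob <- prob_drug[drug_of]
  y <- rbinom(M, 1, prob)

  labels <- tibble(sample_id = rownames(X), label = as.integer(y),
                   group_id = drug_ids[drug_of])

  rate <- spec$term_rate * ifelse(seq_len(n) %in% informative,
                                  spec$frequency_boost, 1)
  sets <- vector("list", spec$n_terms)
  for (k in seq_len(spec$n_terms)) {
    member <- runif(n) < rate
    if (!any(member)) member[sample.int(n, 1)] <- TRUE
    sets[[k]] <- gene_ids[member]
  }
  names(sets) <- sprintf("BP%03d", seq_len(spec$n_terms))
  gene_sets <- gene_set_collection(sets)

  out <- list(
    expression = X,
    labels = labels,
    adjacency = A,
    gene_sets = gene_sets,
    truth = list(informative = gene_ids[informative], u = setNames(u, drug_ids),
                 kappa = kappa, eta = setNames(eta, drug_ids),
                 prob = setNames(prob, rownames(X)),
                 membership_rate = setNames(rate, gene_ids)),
    spec = spec
  )
  class(out) <- "biogl_dataset"
  out
}

#' @export
print.biogl_dataset <- function(x, ...) {
  cat(sprintf("<biogl_dataset> %d samples x %d genes, %d drugs, %d informative genes, prevalence %.2f\n",
              nrow(x$expression), ncol(x$expression), x$spec$n_drugs,
              length(x$truth$informative), mean(x$labels$label)))
  invisible(x)
}

#' AUC of the generative oracle
#'
#' The AUC attained by scoring each sample with its true label probability —
#' the ceiling any classifier can reach on a given synthetic dataset.
#'
#' @param dataset A `biogl_dataset`.
#' @return Scalar AUC.
#' @export
oracle_auc <- function(dataset) {
  compute_metrics(dataset$labels$label, dataset$truth$prob)$auc
}

#' Generate a synthetic replicate set for consensus collapsing
#'
#' Replicates are a shared nonnegative (FPKM-like, log-normal) ground-truth
#' profile plus iid Gaussian noise, truncated at zero. With `outlier = TRUE`
#' the last replicate's values are randomly permuted across genes, destroying
#' its rank agreement with the others.
#'
#' @param spec A [synthetic_spec()] (`n_genes`, `noise_sd`,
#'   `replicates_per_compound`, `seed` are used).
#' @param outlier Corrupt one replicate?
#' @return List with `profiles` (R x N matrix), `truth` (length-N vector) and
#'   `compound_id`.
#' @export
generate_replicate_set <- function(spec, outlier = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- spec$replicates_per_compound
  if (outlier && R < 2) stop_validation("outlier injection needs at least 2 replicates")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("G%03d", seq_len(n))
  truth <- setNames(rlnorm(n, meanlog = 1, sdlog = 1), gene_ids)
  profiles <- matrix(rep(truth, each = R) + rnorm(R * n, sd = spec$noise_sd),
                     R, n, dimnames = list(paste0("rep", seq_len(R)), gene_ids))
  profiles[profiles < 0] <- 0
  if (outlier) profiles[R, ] <- profiles[R, sample.int(n)]
  list(profiles = profiles, truth = truth, compound_id = "synthetic_compound")
}

#' Write a synthetic fixture bundle to a directory
#'
#' Emits expression TSV, labels TSV, edge-list TSV, GMT gene sets and a
#' ground-truth JSON for a generated dataset.
#'
#' @param dataset A `biogl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "biogl_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- write_edge_list(dataset$adjacency)
  utils::write.table(edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(dataset$gene_sets), function(id) {
    paste(c(id, attr(dataset$gene_sets, "term_names")[[id]],
            dataset$gene_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
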