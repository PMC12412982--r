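# bioglgcn

Graph-learning graph convolutional networks for predicting drug-induced
liver injury (DILI) from landmark-gene transcriptomic profiles.

## What it does, and for whom

Toxicogenomic screens summarize a compound's effect as a z-score-like
differential-expression signature over a panel of landmark genes. `bioglgcn`
is for computational toxicologists who want to classify such signatures as
hepatotoxic or not while exploiting gene–gene structure: instead of feeding
genes independently into a classifier, it propagates each gene's signal over
a gene–gene graph — and, crucially, *learns* that graph rather than taking a
protein–protein interaction (PPI) database at face value.

The core is a biological graph-learning (BioGL) layer. Given the expression
matrix *G* (samples × *N* genes), a STRING-derived adjacency prior *A*
(confidence ≥ 0.7, unit diagonal), and a per-gene enrichment-frequency
vector *p*, it produces a row-stochastic learned graph

> *S*<sub>ij</sub> = *A*<sup>φ</sup><sub>ij</sub> exp(σ(αᵀ((*p*<sub>i</sub> − *p*<sub>j</sub>)(g̃<sub>i</sub> − g̃<sub>j</sub>)))) / Σ<sub>j</sub> (·),  g̃ = *G*ᵀ*W*<sub>g</sub>

with Σ<sub>j</sub> *S*<sub>ij</sub> = 1, *S*<sub>ij</sub> ≥ 0, and
support(*S*) ⊆ support(*A*). Two graph convolutional layers
*X*<sup>(l+1)</sup> = σ(*S* *X*<sup>(l)</sup> *W*<sup>(l)</sup>), a flatten
stage and three fully connected layers with softmax perform the
classification. Training minimizes the joint loss

> L = L₁ + λ·L₂,  L₁ = Σ<sub>ij</sub> ‖(*p*<sub>i</sub> − *p*<sub>j</sub>)(g̃<sub>i</sub> − g̃<sub>j</sub>)‖² *S*<sub>ij</sub> + γ‖*S*‖²_F + β‖*S* − *A*<sup>φ</sup>‖²_F

with λ·L₂ the cross-entropy term, by Adam with hand-derived analytic
gradients (verified against finite differences in the test suite).

The gene frequencies *p* come from enrichment counting: per profile, DEGs
are genes with |z| ≥ 2; a gene-set term is enriched as soon as it overlaps
the DEG set; a gene's raw frequency is the mean number of enriched terms
containing it, min–max normalized.

The package also implements the scoring path for new compounds: MODZ
consensus collapsing of biological replicates (Spearman-weighted, weights
summing to 1) and log2 relative expression against a control consensus,
followed by `predict_dili()` with the conventional high (> 0.8) / low
(< 0.4) DILI-score bins. A synthetic-data generator with planted
graph-modulated signal makes the whole pipeline testable offline.

## Worked example

```r
library(bioglgcn)

# a synthetic benchmark: 600 profiles x 60 genes from 30 drugs, with a
# planted connected set of informative genes driving the labels
ds <- generate_dataset(synthetic_spec(seed = 1))
ds
#> <biogl_dataset> 600 samples x 60 genes, 30 drugs, 10 informative genes, prevalence 0.50

freq <- gene_frequencies(ds$expression, ds$gene_sets)
head(freq, 3)
#> # A tibble: 3 × 3
#>   gene_id   raw normalized
#> 1 G001    4.56      0.776
#> 2 G002    0.242     0.0341
#> 3 G003    0.207     0.0280

cfg <- model_config(hidden_dims_gcn = c(16, 8), hidden_dims_fc = c(64, 32, 2))
cv <- run_cross_validation(ds$expression, ds$labels, ds$adjacency, freq,
                           cfg, k = 5, seed = 1)
cv
#> <biogl_cv> 5-fold cross-validation (none model)
#> mean metrics:
#>  accuracy specificity sensitivity     f1    auc
#>    0.8383      0.8625      0.8058 0.8247 0.9143
```

The folds are grouped by drug, so profiles of one compound never straddle a
train/test boundary; the mean held-out AUC of 0.914 approaches this
dataset's generative ceiling (`oracle_auc(ds)` = 0.965). A final model on
all data exposes the learned graph and scores new profiles:

```r
fit <- fit_biogl_gcn(ds$expression, ds$labels$label, ds$adjacency, freq,
                     cfg, seed = 1)
graph_stats(fit$S)
#> # A tibble: 1 × 5
#>   clustering_coefficient density n_nodes n_edges edge_threshold
#> 1                  0.137   0.143      60     253         0.0147

predict_dili(fit, new_profiles)
#> # A tibble: 4 × 3
#>   compound_id     score bin
#> 1 compound_1  0.000114  low
#> 2 compound_2  0.0000415 low
#> 3 compound_3  0.999     high
#> 4 compound_4  0.0000828 low
```

`tidy()`, `glance()` and `autoplot()` methods cover the fitted model and the
cross-validation result; `export_features()` extracts penultimate-layer
embeddings. A command-line interface (`inst/cli/bioglgcn`) wires the same
functions into `simulate`, `build-ppi`, `gene-freq`, `consensus`, `train`,
`predict` and `eval` subcommands.

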