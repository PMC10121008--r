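# spectromics

Graph-convolutional classification of disease status from multi-omics data
on protein–protein interaction (PPI) networks, with network refinement,
Shapley-value interpretation, and pathway enrichment — in one R package,
testable end to end on synthetic data.

## Who this is for

Computational biologists who have (a) a weighted PPI network (e.g. a
STRING-style edge list thresholded at confidence 0.4), (b) one or more omics
matrices (samples × features, e.g. paired transcriptomics and proteomics on
the same gene set), and (c) binary phenotype labels — and who want a
classifier that exploits the interaction structure instead of treating
features as exchangeable columns, plus an account of *which* genes/proteins
drove the predictions.

## The model

Node signals are filtered in the graph spectral domain. With Laplacian
`L = D − A = U Λ Uᵀ`, convolution is `y = U g(Λ) Uᵀ x`, approximated by a
Chebyshev polynomial filter

```
g_θ(Λ̃) = Σ_{k=0}^{K−1} θ_k T_k(Λ̃),   Λ̃ = 2Λ/λ_max − I,
T_k(x) = 2x T_{k−1}(x) − T_{k−2}(x),  T_0 = 1, T_1 = x,
```

evaluated with the sparse recurrence in `O(K|E|)` per signal — the
eigendecomposition is never formed outside of tests. The classifier stacks
two such layers (32 filters; orders 10 and 2), each followed by batch
normalization, ReLU, and average pooling over a Graclus-style coarsening
hierarchy (zero-valued pseudo nodes pad singleton lineages so stride-2
pooling is exact). Filter weights are shared across omics channels; channel
feature maps are concatenated and fed to fully connected layers (64, 64) and
a softmax. Training: Adam (lr 0.001, ×0.95 every 10 steps), dropout 0.3, L2
5e-4, 25 epochs, early stopping; evaluation: a held-out stratified 20% test
set and 4-fold cross-validation on the remainder, reporting accuracy and F1
(mean ± SE over folds) plus paired t-tests against baselines.

Around the classifier:

- **`refine_network()`** — prior-weighted graphical lasso: penalized inverse
  covariance with a discounted penalty on prior-network edges, a 40-value
  log-spaced λ path, fold-wise held-out BIC, and one-SE selection.
- **`shap_explain()`** — sampling-based Shapley attribution of class
  probabilities (1200 coalitions per sample by default, training set as
  background), with `rank_features()`, `extract_subnetwork()` (top-30
  sub-adjacency, isolated nodes dropped) and per-sample `local_report()`.
- **`fisher_enrichment()`** — one-sided hypergeometric over-representation of
  the top nodes against GMT annotation sets with Benjamini–Hochberg FDR.
- **`make_benchmark()`** — seeded synthetic world: a PPI-like graph, a
  Gaussian graphical model consistent with it, and two correlated omics
  channels whose class signal is a mean shift on a planted connected
  subnetwork.

See `vignettes/spectromics-methods.Rmd` for assumptions, parameter
semantics, and design decisions.

## Worked example

```r
library(spectromics)

spec <- synth_spec(p = 80, n = 200, graph_model = "scale_free", avg_degree = 4,
                   signal_size = 10, delta = 1, rho = 0.5, seed = 42)
ds  <- make_benchmark(spec)
cfg <- model_config(epochs = 12, batch_size = 32, seed = 42)

cv <- cross_validate(ds$tensor, ds$graph, cfg)
bl <- run_baselines(ds$tensor, cv$plan, cfg, baselines = "mlp")
compare_models(cv, bl$mlp$fold_metrics$accuracy)

best <- cv$models[[which.max(cv$fold_metrics$accuracy)]]
std  <- standardize_omics(ds$tensor, which(!is.na(cv$plan$fold)))
flat <- flatten_tensor(std)
expl <- shap_explain(function(m) predict_proba(best, m),
                     flat[which(!is.na(cv$plan$fold)), ],
                     flat[head(cv$plan$test, 6), ],
                     n_samples = 400, seed = 42, max_background = 8)
rk  <- rank_features(expl)
sub <- extract_subnetwork(rk, ds$graph, top_k = 20)
```

Output from this exact script:

```
cv_result: accuracy 0.9313 +/- 0.0062, F1 0.9307 +/- 0.0065 (4 folds)
MLP baseline: accuracy 0.8688 +/- 0.0188
paired t-test: t = 3.873, p = 0.0305
        feature      score
1 g0054_protein 0.05558355
2    g0054_mrna 0.04541952
3    g0044_mrna 0.04442662
4    g0013_mrna 0.04290663
5 g0006_protein 0.04212207
top-20 subnetwork: 18 connected nodes in 2 component(s);
8 of 10 planted nodes ranked in the top 20
```

Reading it: the graph model reaches 93% test accuracy versus 87% for a
structure-blind MLP on identical splits (paired t-test across folds,
p = 0.03). The Shapley ranking is dominated by planted signal nodes — note
`g0054` appears through both its protein and mRNA channel — and the induced
top-20 subnetwork recovers 8 of the 10 planted nodes.

The same flow runs from the shell via the bundled CLI
(`inst/cli/spectromics.R`) with `simulate`, `refine`, `train`, `explain`,
`enrich`, and `run` subcommands, or programmatically via
`run_pipeline(run_config(...))`, which writes TSV artifacts and a JSON
manifest per stage.

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic benchmark from scratch and
drives the entire pipeline (simulate → refine → train/CV → explain → enrich)
against the installed package, then writes its target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
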