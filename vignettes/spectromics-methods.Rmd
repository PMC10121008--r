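---
title: "Methods: graph-convolutional multi-omics classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-convolutional multi-omics classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Blood-based omics profiles (e.g. paired transcript and protein measurements
on the same gene set) carry disease signal that is organized by molecular
interaction structure: genes act through pathways, and a protein--protein
interaction (PPI) network is a reasonable prior for which features co-vary
and co-act. `spectromics` classifies samples (case vs control) from one or
more omics matrices while exploiting a weighted PPI graph, and then explains
the trained classifier feature-by-feature. Every stage is usable on its own;
`run_pipeline()` chains them.

# Spectral graph convolution

Let the graph on the $p$ measured features have weighted adjacency $A$ and
weighted degree matrix $D$. The combinatorial Laplacian $L = D - A$ is
symmetric positive semidefinite with eigendecomposition $L = U \Lambda U^T$.
The graph Fourier transform of a node signal $x \in \mathbb{R}^p$ is
$\hat x = U^T x$, and spectral filtering is multiplication in that basis:
$y = U\, g(\Lambda)\, U^T x$.

Forming $U$ costs $O(p^3)$ and is avoided in training. Instead the filter is
a degree-$(K{-}1)$ Chebyshev polynomial
$g_\theta(\tilde\Lambda) = \sum_{k=0}^{K-1} \theta_k T_k(\tilde\Lambda)$ on
the rescaled spectrum $\tilde L = 2L/\lambda_{\max} - I$ (eigenvalues in
$[-1, 1]$), evaluated by the recurrence
$T_k(x) = 2 x T_{k-1}(x) - T_{k-2}(x)$, $T_0 = 1$, $T_1 = x$. Each term is a
sparse matrix--vector product, so filtering costs $O(K|E|)$ per signal, and a
$K$-term filter is exactly $(K{-}1)$-hop local. The eigendecomposition
(`spectral_basis()`) exists in the package only as an analysis tool and as
the dense oracle in the test suite; `cheb_filter()` never forms it.

A note on the rescaling: we use the standard form $2L/\lambda_{\max} - I$.
One additive bias per output channel follows each filter (a common
convention the surrounding literature leaves implicit); this is stated so
that parameter counts are reproducible: a layer with order $K$, $C_{in}$
input and $C_{out}$ output channels has $K \cdot C_{in} \cdot C_{out}$
weights plus $C_{out}$ biases.

# Coarsening and pooling

Pooling needs a cluster structure. `graclus_coarsen()` uses greedy edge
matching: nodes are visited in ascending weighted-degree order (ties broken
by a seeded shuffle — matching variants differ here, and determinism was the
requirement), and each unmatched node merges with the unmatched neighbour
maximizing the normalized-cut score $w_{ij}(1/d_i + 1/d_j)$. Unmatched nodes
survive as singletons. After the requested number of levels, a balanced tree
is built: each coarse node receives exactly `pool_size` children, and short
lineages are padded with *fake* (pseudo) nodes that carry zero signal and no
edges. The level-0 permutation then makes siblings contiguous, so pooling is
plain stride-2 averaging. The number of fake nodes is an emergent property
of the matching on the given graph, not a constant.

Two averaging conventions are offered. The default divides every block by
`pool_size` with fakes contributing zeros — the "neutral value" convention.
Because zero-fakes bias block means downward where padding occurred,
`real_average` (divide by the number of real leaves) is available; the
default was kept as the primary convention deliberately. Convolution may
write nonzero values into fake positions (they are graph-isolated but the
affine bias and batch norm touch them); this is accepted and they vanish
from influence through pooling granularity and training.

# The classifier

Per omics channel: input batch normalization (per node), then two graph-conv
layers — Chebyshev filter, batch normalization (per filter), ReLU, average
pool 2 — with 32 filters each and polynomial sizes 10 and 2. All trainable
parameters are shared across channels ("shared kernels"): each channel is an
independent forward pass through the same filters, and only the running
batch-norm statistics are tracked per channel, since they are properties of
the data, not parameters. The channel feature maps are concatenated
channel-major, flattened, and passed through fully connected layers
(64, 64) to a 2-class softmax; the softmax output layer is counted as the
third fully connected layer. A `"joint"` mode treating the omics as input
channels of one filter bank exists as a configurable alternative.

Training minimizes cross-entropy plus $\ell_2$ (5e-4) on weight matrices
with Adam (lr 0.001, staircase decay 0.95 every 10 optimizer steps), dropout
0.3 on the hidden FC layers, 25 epochs, and early stopping on validation
loss with patience 5, restoring the best weights. Batch size defaults to 64.
Of these, batch size, patience, and the decay interpretation ("10
iterations" read as optimizer steps) are choices this package fixes and
exposes in `model_config()`; the rest are the published defaults.

The evaluation protocol (`cross_validate()`): a stratified 20% test set is
held out once (floor rounding, stratification by label), the remaining 80%
is split into 4 stratified folds, one model is trained per fold (that fold
as validation), and all four models are scored on the fixed test set;
accuracy and F1 are reported as mean ± SE over folds. Standardization
(sample SD, $n-1$) is fitted on each model's training rows only and applied
to validation and test — leakage hygiene the protocol description leaves
unstated. `compare_models()` is a two-sided paired t-test on fold-wise
accuracies; zero-variance differences are flagged degenerate rather than
producing a spurious statistic.

Baselines (`run_baselines()`) see exactly the same splits on flattened
`n x (p*C)` features: the MLP (same FC stack, no graph) ships with the
package; random forest, SVM and gradient boosting dispatch to their usual
packages and are skipped with a warning when those are not installed.

No deep-learning framework is used: forward and backward passes are written
against base matrix algebra with small compiled kernels (batch norm, ReLU,
strided pooling, and the graphical-lasso coordinate descent). CPU
determinism under a seed is part of the contract; at inference the eval-mode
batch norm is folded into the convolution weights, which is exact.

# Prior-weighted network refinement

A generic interaction database is not condition-specific. The refinement
stage estimates a sparse Gaussian graphical model from expression samples,
discounting the penalty on node pairs already present in the prior network:
maximize $\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{ij} W_{ij}
|\Theta_{ij}|$ with $W_{ij} =$ `prior_factor` (default 0.1) on prior edges,
1 elsewhere, 0 on the diagonal. With `prior_factor = 1` this is exactly the
standard graphical lasso, verified in tests against an independent ADMM
solver. The published method this stage stands in for is specified in a
separate prior work whose internals are not reproduced here; the per-edge
penalty weighting is a documented, pluggable stand-in behind the same
interface, so a faithful implementation can be swapped in. Whether that
method thresholds or re-symmetrizes its output, and its exact $\lambda_{\max}$
formula, are unknowable from the sources available and were not guessed.

The penalty path has 40 log-spaced values from $0.01\,\lambda_{\max}$ to
$\lambda_{\max} = \max_{i \ne j} |S_{ij}|$ (the smallest penalty that fully
sparsifies). Selection mixes the two stated ingredients — BIC and 4-fold
cross-validation — as fold-wise held-out BIC:
$\mathrm{BIC}_f(\lambda) = -2\,\ell_{\text{held-out}} + \log(n_f)\, k$,
where $k$ counts nonzero off-diagonal pairs once and $n_f$ is the held-out
fold size (the $n$ of the likelihood actually scored — a deliberate reading,
stated here because conventions differ). The one-SE rule then picks the
largest (sparsest) $\lambda$ whose mean BIC lies within one standard error
of the minimum. Solver tolerances: convergence when the maximum parameter
change between sweeps falls below 1e-4 (200 sweeps cap); a
non-positive-definite intermediate triggers one retry with a 1e-6 diagonal
jitter, then failure; support is read at $|\Theta_{ij}| > 10^{-8}$.

# Interpretation

`shap_explain()` is a sampling (kernel-style) Shapley estimator over the
flattened node-by-channel features, treating the classifier as a black-box
probability function (class-1 probability, matching the "output value"
semantics of per-sample force decompositions; the pre-softmax score was the
other candidate and probability was fixed deliberately, with all features
perturbed jointly across omics). Per explained sample, 1200 coalitions are
drawn by default — all $2^M - 2$ when exhaustively enumerable within the
budget, which makes small cases exact — absent features are imputed from
background rows, and a weighted linear surrogate is solved under the
additivity constraint, so base value plus attributions reconstruct the model
output exactly (up to a $10^{-10}$-scale ridge used for numerical safety).
The background defaults to the training set, summarized to at most 100
k-means medoids when larger; this cap is a documented tractability knob, and
the test suite runs with smaller budgets (stated in the tests) to fit desk
hardware.

Global ranking is the mean absolute attribution over explained samples
(ties broken by feature name); `extract_subnetwork()` collapses channel
features to nodes by maximum score, induces the top-$k$ (default 30)
sub-adjacency, removes nodes left without connections, and enumerates
components. `local_report()` gives the signed per-sample decomposition with
a running sum from the base value.

# Enrichment

`fisher_enrichment()` is classic one-sided over-representation: for a term
with $K$ members in the declared background of $N$ features and a top set of
size $n$ containing $s$ of them, $p = P(X \ge s)$,
$X \sim \mathrm{Hypergeom}(N, K, n)$, with $\mathrm{expected} = Kn/N$ and
Benjamini--Hochberg control (significance convention FDR < 0.05). The
"greater" side is fixed (enrichment, not depletion). The background is the
declared feature universe — the features the model actually saw — rather
than the annotation source's own universe; published tables computed with
annotation-feasible backgrounds can therefore differ by a few percent, which
is why the worked-example checks carry a 5% relative tolerance. No term
hierarchy decorrelation is attempted.

# The synthetic world

`synth_spec()` fixes the stated world the generator draws: a PPI-like graph
(scale-free by default — interaction networks are heavy-tailed — with
Erdős–Rényi and block models available), edge confidences uniform on
[0.4, 1] to mimic a medium-confidence-thresholded network, and a Gaussian
graphical model whose precision is diagonally dominant on the edge pattern
(hence positive definite by construction). Class signal is a mean shift of
$\delta$ marginal SDs on a *connected* planted subnetwork, grown by BFS —
connectedness is the property a graph convolution can exploit, so placing
signal on scattered nodes would not test the claim. The protein channel is
$\rho \cdot \text{mRNA} + \sqrt{1-\rho^2} \cdot (\text{independent draw with
the same class mean})$, so both channels are informative and the
cross-channel correlation at null nodes is $\rho$, reflecting imperfect
mRNA–protein coupling.

Defaults (p = 200, n = 400, 12 signal nodes, $\delta$ = 0.8, $\rho$ = 0.5,
average degree 6, balanced classes, seed 7) are the repository's standard
benchmark. Average degree 6 is this package's choice of a sparse but
connected regime at p = 200. What a green test on this world establishes:
that the pipeline learns graph-structured signal, that the graph prior beats
a structure-blind MLP there, and that attribution ranks planted nodes
highly. What it does not establish: performance on real cohorts — real omics
have heavier tails, batch structure, label noise, confounders, and
mRNA–protein coupling that varies per gene, none of which are emulated.

# Numerical and degenerate-input choices

- `lambda_max` of a Laplacian: dense symmetric eigensolver for $p \le 2000$,
  power iteration (tol 1e-6, 500 iterations) beyond.
- Edgeless (all-fake) coarse levels would have $\lambda_{\max} = 0$; the
  rescaled operator is taken at its limit $-I$.
- Normalized Laplacian: zero-degree rows stay identity rows.
- STRING-style integer scores are detected by any score > 1 and divided by
  1000; duplicate/reciprocal edges keep the maximum score; self-loops drop.
- Constant features are centered, warned about, and not scaled.
- F1 with an empty denominator is 0; paired t-tests on zero-variance
  differences are flagged rather than computed.
- All randomness flows through explicit seeds; stage seeds derive from the
  global seed as `seed + 97 * stage_index` so stages can be rerun alone.

# Known limitations

Training is CPU-bound R + BLAS with compiled kernels — adequate at benchmark
scale (hundreds of nodes, hundreds of samples), not at tens of thousands of
nodes. The kernel explainer's cost is linear in explained samples ×
coalitions × background size; budget accordingly. The refinement stage is a
stand-in for a published augmented estimator (see above). Edge weights are
used as given (confidence scores as weights, with `binarize` available)
because the sources do not state which convention was used upstream.
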