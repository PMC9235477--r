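# glideppi

Sequence-based prediction of protein–protein interactions (PPI),
co-supervised by network topology.

## What this package is for

Experimental PPI networks are incomplete, and the two classic families of
predictors see different halves of the problem. Sequence-based ("bottom-up")
models predict binding from the two amino-acid sequences alone, so they work
for proteins nobody has assayed — but they ignore the known network.
Network-based ("top-down") link predictors exploit the topology of the known
network — but are undefined for proteins outside it. `glideppi` implements,
in R, a synthesis for researchers studying interactomes of model and
non-model organisms:

* **GLIDE network scoring** — a link-plausibility score
  `GLIDE(p,q) = exp(α·u/(u+β))·CWN(p,q) + u` combining a local
  common-weighted-neighbour term (CWN) with a global diffusion-state
  proximity `u = 1/DSD(p,q)` (defaults α = 0.1, β = 1000). The diffusion
  states are the closed-form resolvent `(I − γ(P − W))⁻¹` of the
  random-walk operator, validated in the tests against a truncated-walk
  oracle.
* **A contact-map sequence model** — a convolutional architecture over
  per-residue embeddings (pluggable embedder; a deterministic hash-window
  stand-in ships for offline use) that predicts an interpretable
  inter-protein contact map and an interaction probability
  (reference hyperparameters d = 100, h = 50, filter width 7, pooling 9).
  Forward and backward passes are hand-written RcppArmadillo kernels.
* **Network-co-supervised training** — the multi-objective loss
  `L = λ(L_BCE + g_p·L_GLIDE) + (1−λ)·L_MAG`, where `L_GLIDE` is
  cross-entropy against GLIDE scores binarised at the `g_t`-th percentile
  (defaults λ = 0.05, g_p = 0.2, g_t = 92.5; at g_p = 0 the loss reduces
  exactly to the plain sequence-model loss). Training sets use 10:1
  negative sampling.
* **A hybrid score** `GLIDE(p,q) + w·ŷ(p,q)` for species with a partial
  network, with `w` calibrated as a ratio of logistic-regression
  coefficients (shipped default w = 0.3268).
* **Evaluation protocols for imbalanced link prediction** — AUPR (step-wise,
  tie-grouped), AUROC, FPR at fixed recall, degree- and distance-stratified
  breakdowns, hub filtering (degree ≥ 21), and a spanning-tree-protected
  network sparsification benchmark.
* **Seeded synthetic benchmark generators** — hubby community networks,
  interface-motif sequences with learnable pair signal, 10:1 labels, and a
  planted-mislabel mechanism for studying the co-supervision effect.

## A worked example

```r
library(glideppi)

# a fully synthetic, seeded benchmark: network + sequences + labelled pairs
bench <- synth_benchmark(synth_benchmark_config(length_range = c(30, 60)),
                         seed = 1)
bench$network
#> <ppi_network: 70 proteins, 157 interactions>

# GLIDE scores on the training network, binarised into supervision targets
train <- make_glide_targets(network_edges(bench$network)[, 1:2],
                            bench$train, g_t = 92.5)
attr(train, "glide_threshold")
#> [1] 0.4856049
table(target = train$glide_target, label = train$label)
#>       label
#> target    0    1
#>      0 1017    0
#>      1   83  111

# train the tiny-configuration model with co-supervision
embedder <- hash_embedder()                       # deterministic stand-in
emb <- embed_proteins(bench$sequences, embedder)
model <- seq_model(model_config(projection_dim = 20, hidden_dim = 10,
                                embedder_tag = embedder_tag(embedder),
                                seed = 1),
                   embed_dim = embedder_dim(embedder))
fit <- train_model(model, train, emb,
                   loss_config(lambda = 0.05, g_p = 0.2, g_t = 92.5),
                   train_config(epochs = 10, seed = 1),
                   validation = bench$val)
max(fit$history$val_aupr)
#> [1] 0.1864834

# a random ranking at this 1:10 class ratio would sit at AUPR ~ 0.091;
# the trained model roughly doubles it. Evaluate on the test split:
preds <- predict_pairs(fit$model, bench$test, emb)
evaluate(bench$test$label, preds$score)
#> <eval_report: AUPR 0.1705, AUROC 0.7093 (23+/235-)>
```

The contact map behind any single prediction is available via
`predict_interaction()`, whose entries (in [0, 1]) localise the predicted
interface.

There is also a command-line surface over the same functions (installed to
`exec/glideppi`), with subcommands `glide`, `train`, `predict`, `hybrid`,
`evaluate`, `synth` and `sparsify`; every run writes a JSON manifest
sufficient to replay it.

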