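---
title: "Network-co-supervised sequence-based PPI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-co-supervised sequence-based PPI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glideppi)
```

## The problem

Predictors of physical protein–protein interaction (PPI) fall into two
camps. *Bottom-up* methods look only at the two amino-acid sequences and ask
whether they could bind; they generalise to proteins nobody has assayed, but
ignore everything the known interaction network says. *Top-down* link
predictors score a candidate pair from the topology of the existing PPI
network; they are strong inside a well-mapped network but cannot say
anything about a protein absent from it. `glideppi` implements a synthesis:
a sequence-based convolutional model whose *training* is co-supervised by a
graph-theoretic link-plausibility score, plus a calibrated hybrid score for
species where a partial network exists at prediction time.

## The GLIDE link score

For a pair $(p, q)$ on a weighted undirected network, the GLIDE score is

$$\mathrm{GLIDE}(p,q) \;=\; \exp\!\Big(\frac{\alpha\, u(p,q)}{u(p,q) + \beta}\Big)\,
\mathrm{CWN}(p,q) \;+\; u(p,q),$$

with defaults $\alpha = 0.1$, $\beta = 1000$. The two ingredients:

* **CWN** (common weighted normalized), the local term:
  $\mathrm{CWN}(p,q) = \sum_{z \in N(p) \cap N(q)} \big(w(p,z) + w(z,q)\big)
  / d_w(z)$, where $d_w(z)$ is the weighted degree of the shared neighbour
  $z$. It is zero exactly when the pair shares no neighbour and strictly
  increases as shared neighbours are added.
* **$u$**, the global term: the reciprocal of the diffusion state distance
  (DSD). Let $P$ be the row-normalised weighted adjacency (the transition
  operator of the random walk) and $W = \mathbf{1}\pi^\top$ the projector
  onto its stationary distribution. The diffusion-state matrix is the
  resolvent
  $$X(\gamma) = \big(I - \gamma\,(P - W)\big)^{-1},$$
  and the distance between two nodes is the $L_1$ distance between their
  rows of $X$. At $\gamma = 1$ (the default) this equals the converged
  limit of differences of truncated random-walk visit counts, which is how
  the test suite validates it: an independent oracle accumulates
  $\sum_{s \le k} \gamma^s (e_p - e_q)^\top P^s$ and the two constructions
  agree to $10^{-6}$ in $L_1$ on every fixture. One numerical caveat is
  worth recording: on *bipartite* graphs the un-damped partial sums
  oscillate ($-1$ is an eigenvalue of $P$), while the closed form is still
  well defined; oracle comparisons on bipartite fixtures therefore use
  $\gamma < 1$.

With the default $\alpha$ and $\beta$ the exponential multiplier lies in
$(1, e^{0.1}]$, so the local score dominates wherever it is non-zero and the
global term mostly orders pairs that share no neighbours — the regime where
local scores are blind. Pairs in different components get $u = 0$ and the
multiplier at its limit 1; pairs with an endpoint outside the network are
scored 0 and flagged, since graph evidence simply does not exist for them.

The exact algebraic forms of the local and global metrics vary across the
GLIDE literature; the forms above are the package's fixed, documented
choice, and the tests pin their qualitative contract (symmetry, the
zero-local reduction, metric axioms for the distance, oracle equivalence)
rather than any particular constant.

## The sequence model

Each protein is embedded residue-by-residue by a pluggable embedder. In
production one would plug a pretrained protein language model; the package
ships a deterministic *hash-window* embedder (every residue's vector is a
seeded pseudo-random function of the 5-mer window centred on it, $d_0 = 64$)
so that the full pipeline runs and is testable with no downloads. Identical
windows map to identical rows, which is exactly the property the
convolutional stack needs to detect shared sequence features.

The interaction architecture follows the D-SCRIPT reference design:

1. projection of each embedding row to $d$ dimensions (affine + ReLU;
   a dropout knob exists and defaults to 0 so that fixed-seed runs are
   bit-stable),
2. pairwise combination of the projected sequences into an
   $n \times m \times 2d$ feature field (absolute difference and
   elementwise product),
3. an affine + ReLU map to $h$ hidden channels, a $(2w{+}1)^2$ convolution
   and a sigmoid producing the full-resolution $n \times m$ contact map
   $C$,
4. an interaction head that max-pools $C$ with width $l$, sparsifies the
   pooled map by thresholding at its mean plus a learnable multiple of its
   variance, averages the surviving cells and squashes through a sharp
   trainable logistic centred at $0.5$.

Reference hyperparameters: $d = 100$, $h = 50$, filter width $2w+1 = 7$,
pooling width $l = 9$. The contact map is emitted at full resolution
(pooling is internal to the head) with a 1-based residue-index convention
recorded in the prediction metadata. All forward/backward kernels are
hand-written C++ (RcppArmadillo); the backward pass is verified against
central finite differences at relative error $\sim 10^{-7}$.

## The multi-objective loss

$$L \;=\; \lambda\,\big(L_{\mathrm{BCE}} + g_p\,L_{\mathrm{GLIDE}}\big)
 \;+\; (1-\lambda)\,L_{\mathrm{MAG}}$$

* $L_{\mathrm{BCE}}$: binary cross-entropy of the predicted probability
  against the interaction label (probabilities clamped at
  $\varepsilon = 10^{-7}$).
* $L_{\mathrm{GLIDE}}$: binary cross-entropy against the *binarised* GLIDE
  score of the pair, computed on the network defined by the positive
  training examples. Scores are binarised at the $g_t$-th percentile of the
  score distribution over the negative training examples (the set that gets
  scored); a switch allows the pooled population instead. Binarisation
  sidesteps the awkward raw scale of GLIDE scores and lets $g_p$ alone
  calibrate the term against $L_{\mathrm{BCE}}$.
* $L_{\mathrm{MAG}}$: the mean of the predicted contact map — a sparsity
  regulariser that keeps contact maps realistic, and scale-free in the
  sequence lengths.

Defaults: $\lambda = 0.05$, $g_p = 0.2$, $g_t = 92.5$. At $g_p = 0$ the loss
is bit-identical to the plain two-term sequence loss (a property test).
Design choices the source material leaves open, decided here: positive
training pairs take GLIDE target 1 without scoring (each one is an edge of
the scoring network, where the graph evidence is maximal); negatives with an
endpoint off the scoring network contribute nothing to $L_{\mathrm{GLIDE}}$
and are counted, rather than being given target 0 — penalising the model on
absent evidence would be wrong. Training uses Adam at learning rate 0.001,
batch size 25, 10 epochs, per-batch mean loss, always from seeded fresh
initialization; per-epoch validation AUPR is recorded and "best epoch"
means best validation AUPR.

## The hybrid score

When the target species has a partial network, predictions for in-network
pairs can combine both views:

$$\mathrm{hybrid}(p,q) = \mathrm{GLIDE}(p,q) + w \cdot \hat y(p,q),$$

with the GLIDE weight fixed at 1 (only the ratio matters). The weight $w$
is the ratio of logistic-regression coefficients $c_{\mathrm{seq}} /
c_{\mathrm{glide}}$ from an unregularised ML fit (IRLS, tolerance
$10^{-8}$, intercept included — the intercept does not change the ratio) of
the label on the two raw scores; no standardisation, because $w$ is defined
on the raw scales. The shipped default $w = 0.3268$ comes from a
calibration on large-scale held-out human PPI data; recalibrate per species
when labelled pairs disjoint from the GLIDE scoring network are available
(the function takes the caller's attestation of that disjointness and
refuses a non-positive GLIDE coefficient, where the ratio is undefined).

## Evaluation protocols

All evaluation uses the conventions that matter under heavy class
imbalance: AUPR by step-wise (non-interpolated) summation over descending
threshold groups (tie groups enter together — interpolation conventions
move AUPR in the third decimal, so the choice is fixed); AUROC as the
Mann–Whitney concordance probability; FPR at fixed recall from the same
threshold sweep. Random scores give AUPR equal to prevalence (0.091 at
1:10) and AUROC 0.5; the test suite checks the prevalence law at ratios
1:1, 1:10 and 1:50. Stratified views: by maximum endpoint degree (bins
2–5, 6–10, 11–20, ≥21, with an underflow stratum), by unweighted
shortest-path distance, and with hub-incident pairs removed (strict cutoff:
degree ≥ 21 removed).

The sparsification benchmark keeps a seeded random spanning tree (minimum
spanning tree over i.i.d. uniform edge weights — uniformity over spanning
trees is not required, and the construction is recorded in the split
metadata), fills up to round(p·|E|) edges (round half up, tree edges inside
the budget) with a uniform sample of non-tree edges, and defines the
held-out positives as exactly E \ E_p; the test-set builder asserts both
set identities and samples negatives from the non-edges of the *full*
network at 10:1, splitting them by the same p and recording the unused
portion for comparators that consume it.

## The synthetic benchmark

The generator is a pure function of (config, seed) and emulates the
features of real PPI data the methods depend on:

* **Topology**: a preferential-attachment backbone plus densified planted
  communities and a few boosted hubs — degree-heterogeneous, connected,
  spanning the degree strata used by the evaluation module (nodes of
  degree ≥ 21 appear from a few hundred nodes up).
* **Sequences**: uniform random amino-acid background; each true
  interaction is assigned an 8-mer *interface motif* written into both
  endpoint sequences at random non-overlapping slots. A protein of length
  $L$ carries at most ~$L/12$ motifs, so hub proteins carry only a subset
  of their interfaces — their interactions stay sequence-ambiguous, which
  mirrors the real division of labour in which network methods are
  strongest on hubs. Earlier designs with shared family-level motifs were
  rejected because non-interacting proteins of the same community collided
  on motifs too often for the benchmark to carry clean signal.
* **Labels**: network edges are positive; negatives are uniform non-edges
  at 10:1. A noise knob replaces a stated fraction of the *training*
  negatives with planted truly-positive pairs: non-edges with at least two
  common neighbours (so their GLIDE scores are high), at most two per
  protein, whose interface motifs survive the slot cap with priority. This
  reproduces the mislabelled-negative mechanism the co-supervision term is
  hypothesised to mitigate: pairs that look negative to the label but
  positive to both the network and the sequence.
* **Splits**: pair-disjoint train/validation/test at 70/15/15, planted
  mislabels confined to the training negatives so validation stays clean.

Default generator sequence lengths are 50–300 (long enough for width-7
convolutions and width-9 pooling at realistic protein scales).

What passing tests on this benchmark do **not** show: anything about real
proteomes. The motif mechanism is a deliberately learnable caricature of
binding interfaces; real sequence signal is weaker and dirtier, real
networks are larger and ascertainment-biased, and the production embedder
is a pretrained language model rather than a hash. The benchmark
establishes that the machinery — scoring, loss assembly, optimisation,
evaluation — does what it claims, at desk scale.

## Study sizes used by the tests and the acceptance script

The training experiments run on a 70-node benchmark (preferential
attachment with m = 1, hub fraction 0.04, 4 communities at within-community
edge probability 0.08, 10:1 negatives, sequence lengths 30–60) with the
tiny model configuration d = 20, h = 10 (filter width 7, pooling 9 and all
loss/optimiser defaults as above, embedder $d_0 = 64$). These sizes were
chosen once as the smallest configuration at which the learnability probe
and the learning dynamics are comfortably reproducible on one CPU.

* The *smoke test* trains with $g_p = 0.2$ on the clean benchmark and asks
  for best-epoch validation AUPR at least twice the 1/11 random baseline
  within 10 epochs.
* The *co-supervision experiment* plants mislabels into 2% of the training
  negatives (20% of the positive count — a deliberately strong
  unassayed-interaction rate) and compares $g_p = 0.2$ against $g_p = 0$
  across seeds 1–5, median best-epoch validation AUPR, with a
  non-inferiority margin of 0.01 fixed in advance.
* The *hybrid experiment* works at the score level (the hybrid operates on
  scores): labels drawn from a logistic model in a long-tailed graph score
  and a bounded sequence score, $w$ calibrated on one half, AUPR compared
  on the other half.

## Numerical choices and degenerate inputs

Double precision throughout; dense solves via LU (`solve`) on
per-component matrices; BCE clamping $10^{-7}$; IRLS tolerance $10^{-8}$;
percentiles by linear interpolation between order statistics (inclusive,
type 7). Ties in evaluation are grouped, never broken arbitrarily.
Degenerate inputs have defined behaviour: self-loops and malformed records
are rejected with line numbers, single-class metric inputs raise errors,
all-tied scores yield FPR 1 at any achievable recall, an exhausted negative
pool reports the feasible maximum, and a sparsification fraction too small
to hold a spanning tree reports the feasible minimum.

## Known limitations

* The production protein-language-model embedder is consumed through the
  embedder interface but not shipped; all shipped results use the
  deterministic stand-in.
* GLIDE scoring solves a dense linear system per connected component —
  fine for networks of a few thousand nodes, not for proteome-scale dense
  components.
* The trainer is single-threaded CPU code; it is meant for desk-scale
  experiments and tests, not for 400k-pair corpora.
* `sample_negatives` treats unobserved pairs as negative, which is exactly
  the mislabelling the co-supervision term addresses; the two are meant to
  be used together.
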