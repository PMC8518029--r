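---
title: "Higher-order graph convolution for interaction prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order graph convolution for interaction prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hognet)
```

## The problem and the model

Biomedical interaction networks — protein–protein, drug–drug, drug–target,
gene–disease — are incomplete: experiments cover a biased, partial slice of
the true interactome. Link prediction asks for a probability that an
untested pair interacts, using only the observed topology (and, optionally,
node features). Two empirical facts shape the architecture used here. First,
similarity signals live at several path lengths at once: common neighbors
(paths of length 2) help in dense drug–drug networks, while in protein
interactomes it is length-3 paths that carry most of the signal. Second,
average-pooling graph convolutions cannot represent *differences* between
neighborhoods at different distances, only their blends.

The encoder therefore stacks higher-order graph convolution layers. With
`Â = D^(−1/2)(A + I)D^(−1/2)` the normalized adjacency with self-loops, each
layer computes `σ(Â^j H W_j)` for every power `j` in a set
`P = {0, 1, …, k}` and concatenates the blocks column-wise. Because blocks
stay separate, the *next* layer's weights can assign opposite signs to
different distances and learn, say, "similar at 2 hops but dissimilar at 1
hop". Power 0 is the identity: a per-node feature transform. Setting
`P = {1}` gives back a plain GCN layer exactly, and `P = {1, 2}` the
direct-plus-skip scheme of skip-similarity models; both are available as
configurations and serve as baselines in the sweep harness.

The decoder scores a pair through a bilinear form per edge-feature channel,
`e_ij = ELU(z_i' W_b z_j + b)`, followed by a two-layer head with ELU and a
sigmoid. The bilinear tensor can express multiplicative interactions between
embedding coordinates that a concatenation-plus-linear decoder cannot.

All of this is implemented directly in R: the forward pass, the analytic
backward pass and the Adam optimizer are plain `Matrix`/base-R code. The
gradient implementation is verified against central finite differences in
the test suite (relative tolerance `1e-4`), and the encoder against dense
oracle computations.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `powers` | `0:3` | Adjacency powers mixed per layer. `k = 3` captures the length-3 path signal; larger `k` adds cost with little benefit. |
| `d` | 32 | Embedding width per power; output width is `d·|P|` (128 by default). |
| `n_layers` | 2 | Two rounds of mixing reach 6-hop information at `k = 3`. |
| `d_e` | 64 | Bilinear edge-feature channels. |
| `h` | 32 | Head hidden width; the head depth (2) matters more than `h`. |
| `dropout` | 0.1 | Applied to every layer input and to `e_ij`, training only. |
| `learning_rate` | `5e-4` | Adam, conventional `β = (0.9, 0.999)`, `ε = 1e-8`. |
| `batch_size` | 256 | Pairs per gradient step; the full graph is re-encoded each step. |
| `epochs` / `patience` | 50 / 10 | Early stopping on validation AUPRC; the best-epoch parameters are restored. |

Memory contract: one dense `|V| × d·|P|` matrix per layer, plus a
`B × (d·|P|)²` workspace per decoder batch — full-graph encoding is intended
for networks up to a few tens of thousands of nodes.

## Experimental protocol

Positive edges are shuffled and split 7:1:2 (train/validation/test) with
floor/floor/remainder sizes, so the three parts always conserve the edge
set. Negatives are drawn uniformly from the complement of the *entire*
positive edge set — train, validation and test alike — so no negative can
collide with a held-out positive; each split gets as many negatives as it
has positives. Validation and test negatives are frozen; per-epoch
resampling of training negatives exists as an option but is off by default,
because frozen pools make runs exactly reproducible and we observed no
benefit from resampling at these scales. For bipartite networks negatives
are restricted to cross-type pairs by default: same-type pairs are
structurally impossible positives in drug–target or gene–disease data, and
including them would inflate every metric. Both behaviors are switchable
(`sample_negatives(..., bipartite = FALSE)`).

Message passing uses the training edges only. Masking held-out interactions
from the adjacency is as important as masking them from the loss; an encoder
that sees test edges leaks labels.

One master seed derives every stream (split, negative pools, initialization,
shuffling/dropout), keeping all derived seeds small integers. Two runs with
the same seed are bitwise identical.

## Numerical choices

* **AUPRC** is average precision with step interpolation, evaluated at one
  threshold per distinct score. Trapezoidal interpolation of the PR curve is
  rejected deliberately — it overestimates the area, increasingly so for
  small test sets.
* **AUROC** uses midranks, i.e. ties get half credit (the Mann–Whitney
  convention); the implementation provably matches the brute-force pairwise
  estimator.
* **Reliability curves** use 10 equal-width bins by default; empty bins are
  omitted and bin counts always sum to the number of scored pairs.
* **Loss** is the *mean* of per-pair binary cross-entropy over the batch
  (a sum would couple the learning rate to the batch size). Probabilities
  are clamped at `1e-7` from both ends before taking logs.
* **Edge canonicalization**: undirected pairs are stored and scored as
  `(min, max)` index pairs. The bilinear tensor is unconstrained, so raw
  scores are orientation-dependent; canonical ordering makes every reported
  number well-defined. Ranked outputs break score ties by canonical pair
  order so top-N lists are deterministic.
* **Indices** are 1-based internally (the R convention); files carry string
  identifiers only, and node order is first appearance in the input file so
  adjacency matrices rebuild byte-for-byte.
* **L3 normalizer**: the published form of the heuristic divides each
  length-3 path by `√(d_u d_v)` of its two intermediates, with degrees from
  the raw graph (no self-loops); that is what `l3_score()` implements.
  Zero-degree intermediates cannot contribute a path, so no special-casing
  is needed.
* **Degenerate inputs**: an isolated node gets `Â_ii = 1`; a complete graph
  has no negatives to sample (an error reports the available maximum);
  single-class metric inputs raise errors rather than returning arbitrary
  values.

## Design choices where the design was open

* **Layer nonlinearity**: ELU everywhere, matching the decoder's stated
  nonlinearity, with ReLU/tanh switchable in the configuration.
* **Early-stopping metric**: validation AUPRC (the headline ranking metric
  here), with the best checkpoint restored rather than the last.
* **One-hot features** are implemented as a first-layer lookup (`XW = W`
  when `X = I`); a test asserts equivalence with explicit identity features.
* **Head hidden width** 32: the head is deliberately small; its job is to
  bend the bilinear features into a calibrated probability, not to add
  capacity.
* **Xavier-uniform** initialization for every weight matrix; for the
  bilinear tensor each `d* × d*` slice is treated as a square matrix. Biases
  start at zero.

## What the synthetic generators emulate — and what they do not

`generate_sbm()` produces stochastic block models: community co-membership
is recoverable from higher-order neighborhoods, which is exactly the signal
the encoder's `k`-hop mixing is built to exploit, so held-out SBM links are
predictable from topology alone. `generate_bipartite()` plants low-rank
latent structure behind a logistic link, with the intercept calibrated by
bisection to a target density — a drug–target-like benchmark where
cross-type structure, not communities, carries the signal.

Neither generator reproduces the heavy-tailed degree distributions,
clustering, motif spectra or ascertainment bias of real interactomes. A
passing end-to-end test shows the implementation can extract planted
topological signal; it does not certify performance on laboratory data.

One property of SBMs deserves emphasis because it bounds every benchmark
built on them: *conditional on the block assignment, edge indicators are
independent*. Within a block there is literally no topological difference
between a held-out edge and a non-edge; discrimination can come only from
recovering blocks (and from the mild degree signal induced by evaluating
positives drawn among edges against negatives drawn among non-edges). On
sparse settings — e.g. 300 nodes with within/between probabilities
0.08/0.005, the configuration of the packaged benchmark — this ceiling sits
well below what the same model attains on denser or more structured graphs,
and no amount of training can cross it; the training curves show the model
reaching it within a few epochs and then overfitting. The denser worked
example in the README (`p_in = 0.30`, four blocks) illustrates the same
pipeline in a regime where block recovery is easy. Likewise, at very low
training fractions a sparse SBM falls below the community-detectability
threshold, where *every* topological method degrades to chance; comparisons
between configurations remain well-defined but their margins shrink
accordingly.

## Problem sizes

The test suite exercises dense oracles on graphs up to 15 nodes
(exhaustive), property checks on 25–60 node graphs across many seeds, and
end-to-end training on 200–300 node synthetic networks; the acceptance
script runs the 300-node benchmark over three seeds and a two-arm sweep at
10% training edges. These sizes were chosen so the full pipeline —
including the hand-written backward pass — is exercised at realistic width
(`d* = 128`, `d_e = 64`) while a complete run stays in the minutes range on
a single CPU.

## Known limitations

* Full-graph encoding per step: no neighbor sampling or minibatched
  subgraphs, so very large networks (≫ 10⁵ nodes) are out of scope.
* Binary adjacency only; no edge weights, directions or multigraphs.
* No attention-based convolution or inner-product/variational decoders.
* Calibration is reported, not enforced; no post-hoc recalibration
  (temperature scaling etc.) is included.
* Negative "non-interactions" are unverified absences — in real data some
  are undiscovered positives; metrics inherit that label noise.
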