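# hognet

Link prediction on biomedical interaction networks — protein–protein,
drug–drug, drug–target and gene–disease — with a **higher-order graph
convolutional network** and a **bilinear edge decoder**, implemented in base
R with `Matrix` sparse algebra (forward pass, backpropagation and Adam are
written out in full; no deep-learning framework is involved).

It is aimed at computational biologists who have an interaction network as
an edge list, want calibrated probabilities for unobserved pairs, and want
the surrounding experimental protocol — leakage-safe splits and negative
sampling, ranking and calibration metrics, topological baselines and
synthetic benchmarks — handled correctly and reproducibly.

## The model

Given a simple undirected graph with adjacency `A`, let

    Â = D^(−1/2) (A + I) D^(−1/2)

be the symmetrically normalized adjacency with self-connections. A plain GCN
layer is `H' = σ(Â H W)`; its aggregation is limited to immediate neighbors.
Each **higher-order graph convolution (HOGC)** layer instead mixes a whole
set of adjacency powers `P = {0, 1, …, k}`:

    H^(l) = ‖_{j ∈ P} σ( Â^j H^(l−1) W_j^(l) )

where `‖` is column-wise concatenation and `Â^j H` is computed by `j`
successive sparse–dense products (never materializing `Â^j`). Keeping the
per-power blocks separate lets the next layer's weights form *signed*
combinations of neighborhoods at different distances — e.g. the difference
between 1-hop and 2-hop features — which average-pooling GCNs cannot
represent. `P = {1}` recovers GCN exactly; `P = {1, 2}` recovers
direct-plus-skip aggregation.

Two such layers produce embeddings `Z ∈ R^{|V| × d·|P|}` (one-hot input
features by default). A pair `(i, j)` is scored by bilinear fusion and a
small feed-forward head:

    e_ij = ELU( z_i^T W_b z_j + b ),   p_ij = sigmoid( FC2( ELU( FC1(e_ij) ) ) )

trained end-to-end with binary cross-entropy against observed interactions
and uniformly sampled non-interactions (Adam, minibatches of 256, learning
rate 5·10⁻⁴, at most 50 epochs, early stopping on validation AUPRC with
patience 10, Xavier initialization, dropout 0.1).

Also included: the **TCP** common-neighbor baseline (`(A²)_ij`) and the
degree-normalized length-3 path score **L3**
(`Σ_{u,v} A_iu A_uv A_vj / √(d_u d_v)`).

## Worked example

```r
library(hognet)

# a 200-node network with 4 communities: held-out links are predictable
# from topology alone
g <- generate_sbm(200, 4, 0.30, 0.01, seed = 7)
g
#> Interaction graph (unipartite): 200 nodes, 1600 edges
#>   average degree: 16.00

fit <- hogcn(g, seed = 7)   # 7:1:2 split, reference settings
fit
#> Higher-order GCN link predictor
#> HOGCN config: 2 layer(s), powers {0,1,2,3}, d = 32 (d* = 128), d_e = 64, head 32, dropout 0.1, elu
#>   graph: 200 nodes, 1600 edges; split 1120/160/320 (seed 7)
#>   trained 37 epoch(s); best validation AUPRC 0.8045 at epoch 27
#>   test: AUPRC 0.7988  AUROC 0.8522  Brier 0.1497
```

The test line reads: ranking the 320 held-out interactions against an equal
number of sampled non-interactions, the model reaches AUPRC 0.80 and AUROC
0.85 — a randomly chosen true interaction outscores a random non-interaction
85% of the time — and the Brier score 0.15 (mean squared error of the
probabilities; 0.25 is an uninformative constant 0.5). `summary(fit)` adds
the per-bin reliability table, `plot(fit)` the training curves,
`plot(fit, "reliability")` the calibration diagram, and
`predict(fit, pairs = cbind("n007", "n123"))` scores arbitrary pairs.
Message passing uses training edges only, so validation/test interactions
are invisible to the encoder.

Everything is seeded: the master seed derives the split, the negative
samples, the initialization and the shuffling, so a rerun reproduces the fit
bit for bit.

A thin command-line front end over the same functions ships in
`inst/cli/hogcn.R` (subcommands `simulate`, `train`, `evaluate`, `predict`,
`heuristics`, `sweep`).

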