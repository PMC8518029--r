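# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: dense base-R linear algebra and
# scalar loops only.

# Erdos-Renyi graph as a 1-block SBM.
rand_graph <- function(n, p, seed) generate_sbm(n, 1L, p, p, seed = seed)

dense_A <- function(graph) {
  n <- n_nodes(graph)
  A <- matrix(0, n, n)
  for (r in seq_len(n_edges(graph))) {
    i <- graph$edges[r, 1L]; j <- graph$edges[r, 2L]
    A[i, j] <- 1; A[j, i] <- 1
  }
  A
}

dense_norm_adj <- function(graph) {
  A <- dense_A(graph) + diag(n_nodes(graph))
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}

dense_power_apply <- function(Ahat, H, j) {
  out <- H
  for (k in seq_len(j)) out <- Ahat %*% out
  out
}

# Plain GCN layer written independently: sigma(Ahat H W).
plain_gcn_layer <- function(graph, H, W) {
  x <- dense_norm_adj(graph) %*% H %*% W
  ifelse(x > 0, x, exp(x) - 1)
}

brute_tcp <- function(graph, i, j) {
  A <- dense_A(graph)
  sum(A[i, ] * A[j, ])
}

brute_l3 <- function(graph, i, j) {
  A <- dense_A(graph)
  d <- rowSums(A)
  s <- 0
  for (u in seq_len(nrow(A))) {
    for (v in seq_len(nrow(A))) {
      if (A[i, u] == 1 && A[u, v] == 1 && A[v, j] == 1) {
        s <- s + 1 / sqrt(d[u] * d[v])
      }
    }
  }
  s
}

brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Average precision stepped by hand over descending distinct thresholds.
brute_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

brute_bce <- function(p, y) {
  s <- 0
  for (k in seq_along(p)) s <- s - y[k] * log(p[k]) - (1 - y[k]) * log(1 - p[k])
  s / length(p)
}

brute_brier <- function(p, y) {
  s <- 0
  for (k in seq_along(p)) s <- s + (p[k] - y[k])^2
  s / length(p)
}

# Bilinear fusion by explicit double loop over the tensor indices.
brute_bilinear <- function(z_i, z_j, W_arr, b) {
  d_e <- dim(W_arr)[1L]
  out <- numeric(d_e)
  for (m in seq_len(d_e)) {
    s <- 0
    for (p in seq_along(z_i)) {
      for (q in seq_along(z_j)) {
        s <- s + z_i[p] * W_arr[m, p, q] * z_j[q]
      }
    }
    out[m] <- s + b[m]
  }
  ifelse(out > 0, out, exp(out) - 1)
}

# Deterministic graph with a prescribed node and edge count (circulant
# lattice): node i links to i+1, i+2, ... until the edge budget is spent.
lattice_graph <- function(n_nodes, n_edges) {
  stopifnot(n_edges <= n_nodes * (n_nodes - 1) / 2)
  got <- 0L
  rows <- vector("list", 64L)
  k <- 0L
  while (got < n_edges) {
    k <- k + 1L
    i <- seq_len(n_nodes)
    j <- ((i - 1L + k) %% n_nodes) + 1L
    e <- cbind(pmin(i, j), pmax(i, j))
    e <- e[!duplicated(paste(e[, 1L], e[, 2L])), , drop = FALSE]
    take <- min(nrow(e), n_edges - got)
    rows[[k]] <- e[seq_len(take), , drop = FALSE]
    got <- got + take
  }
  edges <- do.call(rbind, rows)
  interaction_graph(edges, nodes = sprintf("n%d", seq_len(n_nodes)))
}
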