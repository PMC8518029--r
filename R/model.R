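#' Model configuration for a higher-order GCN link predictor
#'
#' Collects the architecture hyperparameters: the set of adjacency powers
#' `P` mixed in every encoder layer, the number of layers, the per-power
#' embedding width `d` (so each layer outputs `d * |P|` columns), the
#' bilinear edge-representation dimension `d_e`, the hidden width of the
#' two-layer prediction head, the dropout rate and the layer nonlinearity.
#' The defaults are the reference configuration for biomedical interaction
#' networks: 2 layers, `P = {0, 1, 2, 3}`, `d = 32`, `d_e = 64`.
#'
#' Special cases: `powers = 1` reduces every layer to a plain GCN layer, and
#' `powers = c(1, 2)` to the direct-plus-skip aggregation of skip-similarity
#' models.
#'
#' @param powers ordered distinct nonnegative integers; power 0 is the
#'   identity (the node's own features).
#' @param d embedding width per adjacency power.
#' @param n_layers number of encoder layers (`L >= 1`).
#' @param d_e bilinear edge-feature dimension.
#' @param h hidden width of the prediction head.
#' @param dropout dropout probability applied to layer inputs and the edge
#'   representation during training.
#' @param activation encoder nonlinearity: `"elu"` (default), `"relu"` or
#'   `"tanh"`.
#' @return An object of class `hogcn_config`.
#' @export
hogcn_config <- function(powers = 0:3, d = 32L, n_layers = 2L, d_e = 64L,
                         h = 32L, dropout = 0.1, activation = "elu") {
  powers <- sort(unique(as.integer(powers)))
  if (length(powers) < 1L || any(powers < 0L)) {
    stop("powers must be distinct nonnegative integers")
  }
  d <- as.integer(d); n_layers <- as.integer(n_layers)
  d_e <- as.integer(d_e); h <- as.integer(h)
  if (n_layers < 1L || d < 1L || d_e < 1L || h < 1L) {
    stop("n_layers, d, d_e and h must be >= 1")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  activation <- match.arg(activation, c("elu", "relu", "tanh"))
  structure(
    list(powers = powers, d = d, n_layers = n_layers, d_e = d_e, h = h,
         dropout = dropout, activation = activation,
         d_star = d * length(powers)),
    class = "hogcn_config"
  )
}

#' @export
print.hogcn_config <- function(x, ...) {
  cat(sprintf(
    "HOGCN config: %d layer(s), powers {%s}, d = %d (d* = %d), d_e = %d, head %d, dropout %.2g, %s\n",
    x$n_layers, paste(x$powers, collapse = ","), x$d, x$d_star, x$d_e, x$h,
    x$dropout, x$activation))
  invisible(x)
}

#' Initialize all trainable parameters
#'
#' Weight matrices are drawn from the Xavier-uniform scheme,
#' `U(-a, a)` with `a = sqrt(6 / (n_in + n_out))`; biases start at zero.
#' For the bilinear fusion tensor each `d* x d*` slice is treated as a square
#' matrix (`n_in = n_out = d*`). Identical seeds yield bitwise-identical
#' parameters.
#'
#' Parameter names: `W<l>_<j>` (encoder layer `l`, adjacency power `j`),
#' `Wb` (bilinear tensor flattened to `d_e x d*^2`), `b_b` (bilinear bias),
#' `W_h1`/`b_h1` and `W_h2`/`b_h2` (prediction head).
#'
#' @param config an [hogcn_config()].
#' @param n_nodes number of graph nodes (width of one-hot features).
#' @param n_features feature dimension, or `NULL` for one-hot input.
#' @param seed integer seed.
#' @return Named list of parameter arrays.
#' @export
init_hogcn_params <- function(config, n_nodes, n_features = NULL, seed = 1L) {
  f0 <- as.integer(n_features %||% n_nodes)
  with_seed(seed, {
    params <- list()
    in_dim <- f0
    for (l in seq_len(config$n_layers)) {
      for (j in config$powers) {
        params[[sprintf("W%d_%d", l, j)]] <- xavier_uniform(in_dim, config$d)
      }
      in_dim <- config$d_star
    }
    ds <- config$d_star
    # one d_e x ds^2 matrix; row m is slice m of the fusion tensor, column
    # index (p - 1) * ds + q holds W_b[m, p, q]
    wb <- matrix(stats::runif(config$d_e * ds * ds,
                              -sqrt(6 / (2 * ds)), sqrt(6 / (2 * ds))),
                 nrow = config$d_e)
    params$Wb <- wb
    params$b_b <- rep(0, config$d_e)
    params$W_h1 <- xavier_uniform(config$d_e, config$h)
    params$b_h1 <- rep(0, config$h)
    params$W_h2 <- xavier_uniform(config$h, 1L)
    params$b_h2 <- 0
    params
  })
}

xavier_uniform <- function(n_in, n_out) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -a, a), nrow = n_in, ncol = n_out)
}

# Flattened bilinear matrix <-> d_e x ds x ds array, column c = (p-1)*ds + q.
wb_as_array <- function(Wb, ds) {
  arr <- array(0, dim = c(nrow(Wb), ds, ds))
  for (p in seq_len(ds)) {
    arr[, p, ] <- Wb[, (p - 1L) * ds + seq_len(ds), drop = FALSE]
  }
  arr
}

wb_as_matrix <- function(arr) {
  ds <- dim(arr)[2L]
  Wb <- matrix(0, nrow = dim(arr)[1L], ncol = ds * ds)
  for (p in seq_len(ds)) {
    Wb[, (p - 1L) * ds + seq_len(ds)] <- arr[, p, ]
  }
  Wb
}

#' Apply the j-th normalized-adjacency power to a feature matrix
#'
#' Computes `A_hat^j H` by `j` successive sparse-dense products (right-to-left
#' multiplication), never materializing the dense matrix power. `j = 0`
#' returns `H` unchanged (`A_hat^0` is the identity).
#'
#' @param adj a [normalized_adjacency()] (or bare sparse matrix).
#' @param H numeric matrix with one row per node.
#' @param j nonnegative integer power.
#' @return A base numeric matrix of the same shape as `H`.
#' @export
propagate_power <- function(adj, H, j) {
  M <- as_adj_matrix(adj)
  H <- as.matrix(H)
  if (nrow(H) != nrow(M)) stop("H must have one row per node")
  j <- as.integer(j)
  if (j < 0L) stop("j must be nonnegative")
  for (i in seq_len(j)) H <- as.matrix(M %*% H)
  H
}

#' One higher-order graph convolution layer
#'
#' Computes the column-wise concatenation over the power set
#' `H_out = [ sigma(A_hat^j H W_j) ]_{j in P}` with blocks ordered by
#' ascending `j`. With `powers = 1` this is exactly a plain GCN layer
#' `sigma(A_hat H W)`.
#'
#' @param adj a [normalized_adjacency()].
#' @param H input feature matrix (`|V| x F`).
#' @param W_list list of weight matrices, one per power, all `F x d`.
#' @param powers the adjacency powers, ascending.
#' @param activation nonlinearity name.
#' @param dropout dropout rate applied to `H` when `train = TRUE`.
#' @param train logical; enables dropout.
#' @return Matrix of width `d * length(powers)`.
#' @export
hogc_layer <- function(adj, H, W_list, powers, activation = "elu",
                       dropout = 0, train = FALSE) {
  H <- as.matrix(H)
  powers <- as.integer(powers)
  if (length(W_list) != length(powers)) {
    stop("need one weight matrix per power")
  }
  if (train && dropout > 0) {
    H <- H * matrix(dropout_mask(length(H), dropout), nrow = nrow(H))
  }
  blocks <- vector("list", length(powers))
  for (k in seq_along(powers)) {
    W <- as.matrix(W_list[[k]])
    if (nrow(W) != ncol(H)) {
      stop("shape mismatch for power j = ", powers[k], ": input width ",
           ncol(H), " vs weight rows ", nrow(W))
    }
    blocks[[k]] <- act_forward(propagate_power(adj, H %*% W, powers[k]),
                               activation)
  }
  do.call(cbind, blocks)
}

#' Encode all nodes into embeddings
#'
#' Runs the stacked higher-order convolution layers and returns the final
#' embedding matrix `Z` (`|V| x d*`). With one-hot default features the
#' first layer reduces to `sigma(A_hat^j W_j)` because `I W = W`; this
#' lookup form is used for memory, and is mathematically identical to
#' multiplying by an explicit identity feature matrix.
#'
#' @param graph an `interaction_graph` (used for its feature matrix; pass
#'   `features` to override).
#' @param params parameter list from [init_hogcn_params()].
#' @param config the [hogcn_config()].
#' @param adj optional precomputed [normalized_adjacency()].
#' @param features optional explicit feature matrix; default is the graph's
#'   features, or one-hot if none.
#' @param train logical; enables dropout (stochastic). Evaluation mode is
#'   deterministic for fixed parameters.
#' @return Embedding matrix `Z` of shape `|V| x d*`.
#' @export
encode_nodes <- function(graph, params, config, adj = NULL, features = NULL,
                         train = FALSE) {
  adj <- adj %||% normalized_adjacency(graph)
  X <- features %||% graph$features
  encode_forward(adj, X, params, config, train = train)$Z
}

# Forward pass of the encoder with caches for backpropagation.
# X = NULL means one-hot features (lookup first layer).
encode_forward <- function(adj, X, params, config, train = FALSE) {
  act <- config$activation
  rate <- if (train) config$dropout else 0
  n <- nrow(as_adj_matrix(adj))
  H <- if (is.null(X)) NULL else as.matrix(X)
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    onehot <- is.null(H)
    if (onehot) {
      mask <- if (rate > 0) dropout_mask(n, rate) else NULL
    } else {
      mask <- if (rate > 0) {
        matrix(dropout_mask(length(H), rate), nrow = nrow(H))
      } else NULL
      if (!is.null(mask)) H <- H * mask
    }
    O <- vector("list", length(config$powers))
    Ablk <- vector("list", length(config$powers))
    for (k in seq_along(config$powers)) {
      j <- config$powers[k]
      W <- params[[sprintf("W%d_%d", l, j)]]
      M <- if (onehot) {
        if (is.null(mask)) W else W * mask
      } else {
        if (nrow(W) != ncol(H)) {
          stop("shape mismatch at layer ", l, ", power j = ", j)
        }
        H %*% W
      }
      O[[k]] <- propagate_power(adj, M, j)
      Ablk[[k]] <- act_forward(O[[k]], act)
    }
    layers[[l]] <- list(onehot = onehot, H_in = if (onehot) NULL else H,
                        mask = mask, O = O)
    H <- do.call(cbind, Ablk)
  }
  list(Z = H, layers = layers)
}

# Backward pass through the encoder; dZ is the gradient at the output.
encode_backward <- function(adj, dZ, fw, params, config) {
  act <- config$activation
  grads <- list()
  dH <- dZ
  for (l in rev(seq_len(config$n_layers))) {
    cache <- fw$layers[[l]]
    d <- config$d
    dH_in <- if (cache$onehot) NULL else matrix(0, nrow(cache$H_in), ncol(cache$H_in))
    for (k in seq_along(config$powers)) {
      j <- config$powers[k]
      cols <- (k - 1L) * d + seq_len(d)
      dO <- dH[, cols, drop = FALSE] * act_grad(cache$O[[k]], act)
      G <- propagate_power(adj, dO, j)  # A_hat symmetric: transpose = itself
      nm <- sprintf("W%d_%d", l, j)
      if (cache$onehot) {
        grads[[nm]] <- if (is.null(cache$mask)) G else G * cache$mask
      } else {
        grads[[nm]] <- crossprod(cache$H_in, G)
        dH_in <- dH_in + G %*% t(params[[nm]])
      }
    }
    if (!cache$onehot && !is.null(cache$mask)) dH_in <- dH_in * cache$mask
    dH <- dH_in
  }
  grads
}

#' Bilinear fusion of two node embeddings into an edge representation
#'
#' Computes `e_ij = ELU(z_i^T W_b z_j + b)` componentwise:
#' `e_ij[m] = ELU( sum_{p,q} z_i[p] W_b[m, p, q] z_j[q] + b[m] )`.
#' The fusion tensor is unconstrained, so the raw score is not symmetric in
#' `(i, j)`; all package code evaluates pairs in canonical `(min, max)` order.
#'
#' @param z_i,z_j embedding vectors of equal length `d*`.
#' @param W_b fusion tensor, either a `d_e x d* x d*` array or its flattened
#'   `d_e x d*^2` matrix form (column `(p-1) d* + q`).
#' @param b bias vector of length `d_e`.
#' @return Numeric vector of length `d_e`.
#' @export
bilinear_fuse <- function(z_i, z_j, W_b, b) {
  z_i <- as.numeric(z_i); z_j <- as.numeric(z_j)
  if (length(z_i) != length(z_j)) stop("z_i and z_j lengths differ")
  ds <- length(z_i)
  if (is.matrix(W_b)) {
    if (ncol(W_b) != ds * ds) stop("W_b width must be d*^2")
    # column c = (p-1)*ds + q, q fastest: the vectorized outer product is
    # kronecker(z_i, z_j)
    s <- drop(W_b %*% kronecker(z_i, z_j)) + b
  } else {
    if (!all(dim(W_b)[2:3] == ds)) stop("W_b slices must be d* x d*")
    s <- vapply(seq_len(dim(W_b)[1L]),
                function(m) drop(z_i %*% W_b[m, , ] %*% z_j), 0) + b
  }
  act_forward(s, "elu")
}

#' Interaction probability from an edge representation
#'
#' The two-layer prediction head:
#' `p = sigmoid(W_h2^T ELU(W_h1^T e + b_h1) + b_h2)`, always strictly inside
#' `(0, 1)`.
#'
#' @param e edge representation vector (length `d_e`) or matrix with one row
#'   per edge.
#' @param W_h1,b_h1,W_h2,b_h2 head parameters (`d_e x h`, `h`, `h x 1`,
#'   scalar).
#' @return Numeric vector of probabilities.
#' @export
predict_edge_probability <- function(e, W_h1, b_h1, W_h2, b_h2) {
  E <- if (is.null(dim(e))) matrix(e, nrow = 1L) else as.matrix(e)
  if (ncol(E) != nrow(W_h1)) stop("edge representation width mismatch")
  U <- sweep(E %*% W_h1, 2L, b_h1, "+")
  drop(sigmoid(act_forward(U, "elu") %*% W_h2 + b_h2))
}

# Decoder forward with caches. pairs: canonical index matrix.
decode_forward <- function(Z, pairs, params, config, train = FALSE) {
  ds <- config$d_star
  Zi <- Z[pairs[, 1L], , drop = FALSE]
  Zj <- Z[pairs[, 2L], , drop = FALSE]
  pidx <- rep(seq_len(ds), each = ds)
  qidx <- rep(seq_len(ds), times = ds)
  Outer <- Zi[, pidx, drop = FALSE] * Zj[, qidx, drop = FALSE]
  S <- sweep(Outer %*% t(params$Wb), 2L, params$b_b, "+")
  E <- act_forward(S, "elu")
  mask <- NULL
  if (train && config$dropout > 0) {
    mask <- matrix(dropout_mask(length(E), config$dropout), nrow = nrow(E))
    E <- E * mask
  }
  U <- sweep(E %*% params$W_h1, 2L, params$b_h1, "+")
  V <- act_forward(U, "elu")
  s <- drop(V %*% params$W_h2) + params$b_h2
  list(p = sigmoid(s), Zi = Zi, Zj = Zj, Outer = Outer, S = S, E = E,
       mask = mask, U = U, V = V)
}

# Decoder backward: returns parameter grads and dZ (|V| x d*).
decode_backward <- function(ds_logit, fw, pairs, params, config, n_nodes) {
  ds <- config$d_star
  grads <- list()
  grads$W_h2 <- crossprod(fw$V, ds_logit)
  grads$b_h2 <- sum(ds_logit)
  dV <- ds_logit %*% t(params$W_h2)
  dU <- dV * act_grad(fw$U, "elu")
  grads$W_h1 <- crossprod(fw$E, dU)
  grads$b_h1 <- colSums(dU)
  dE <- dU %*% t(params$W_h1)
  if (!is.null(fw$mask)) dE <- dE * fw$mask
  dS <- dE * act_grad(fw$S, "elu")
  grads$Wb <- crossprod(dS, fw$Outer)
  grads$b_b <- colSums(dS)
  dOuter <- dS %*% params$Wb
  B <- nrow(dOuter)
  arr <- array(dOuter, dim = c(B, ds, ds))  # [b, q, p]
  dZi <- matrix(0, B, ds)
  dZj <- matrix(0, B, ds)
  for (q in seq_len(ds)) dZi <- dZi + arr[, q, ] * fw$Zj[, q]
  for (p in seq_len(ds)) dZj <- dZj + arr[, , p] * fw$Zi[, p]
  dZ <- matrix(0, n_nodes, ds)
  agg <- rowsum(rbind(dZi, dZj), group = c(pairs[, 1L], pairs[, 2L]))
  dZ[as.integer(rownames(agg)), ] <- agg
  list(grads = grads, dZ = dZ)
}

# Full forward in eval mode, chunked so the B x d*^2 buffer stays small.
predict_pairs_prob <- function(adj, X, pairs, params, config,
                               chunk = 1024L) {
  Z <- encode_forward(adj, X, params, config, train = FALSE)$Z
  B <- nrow(pairs)
  p <- numeric(B)
  for (start in seq(1L, B, by = chunk)) {
    ix <- start:min(start + chunk - 1L, B)
    p[ix] <- decode_forward(Z, pairs[ix, , drop = FALSE], params, config,
                            train = FALSE)$p
  }
  p
}

# Loss + gradients for one batch (shared by the trainer and the
# finite-difference tests). Dropout is stochastic when train = TRUE.
hogcn_loss_grads <- function(adj, X, pairs, labels, params, config,
                             train = FALSE) {
  n <- nrow(as_adj_matrix(adj))
  fw_enc <- encode_forward(adj, X, params, config, train = train)
  fw_dec <- decode_forward(fw_enc$Z, pairs, params, config, train = train)
  p <- pmin(pmax(fw_dec$p, 1e-7), 1 - 1e-7)
  B <- length(labels)
  loss <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  ds_logit <- matrix((p - labels) / B, ncol = 1L)
  dec <- decode_backward(ds_logit, fw_dec, pairs, params, config, n)
  enc_grads <- encode_backward(adj, dec$dZ, fw_enc, params, config)
  list(loss = loss, grads = c(enc_grads, dec$grads), p = fw_dec$p)
}
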