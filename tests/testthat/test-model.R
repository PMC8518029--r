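test_that("propagate_power matches dense matrix powers and is linear", {
  g <- rand_graph(10, 0.3, seed = 1)
  adj <- normalized_adjacency(g)
  Ahat <- dense_norm_adj(g)
  H <- matrix(rnorm(10 * 4), 10, 4)

  expect_identical(propagate_power(adj, H, 0), H)
  expect_equal(propagate_power(adj, diag(10), 1), Ahat, tolerance = 1e-10)
  expect_equal(propagate_power(adj, H, 3),
               dense_power_apply(Ahat, H, 3), tolerance = 1e-6)

  H2 <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(propagate_power(adj, 2 * H + 3 * H2, 2),
               2 * propagate_power(adj, H, 2) + 3 * propagate_power(adj, H2, 2),
               tolerance = 1e-6)
  expect_error(propagate_power(adj, matrix(0, 3, 2), 1), "row per node")
})

test_that("a single-power layer reduces to a plain GCN layer", {
  for (s in 1:20) {
    g <- rand_graph(15, 0.25, seed = 100 + s)
    adj <- normalized_adjacency(g)
    H <- matrix(rnorm(15 * 5), 15, 5)
    W <- matrix(rnorm(5 * 3), 5, 3)
    expect_equal(hogc_layer(adj, H, list(W), powers = 1L),
                 plain_gcn_layer(g, H, W), tolerance = 1e-6)
  }
})

test_that("the two-power layer is the skip-similarity block concatenation", {
  for (s in 1:5) {
    g <- rand_graph(15, 0.25, seed = 200 + s)
    adj <- normalized_adjacency(g)
    Ahat <- dense_norm_adj(g)
    H <- matrix(rnorm(15 * 4), 15, 4)
    W1 <- matrix(rnorm(4 * 3), 4, 3)
    W2 <- matrix(rnorm(4 * 3), 4, 3)
    elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
    want <- cbind(elu(Ahat %*% H %*% W1), elu(Ahat %*% Ahat %*% H %*% W2))
    expect_equal(hogc_layer(adj, H, list(W1, W2), powers = c(1L, 2L)),
                 want, tolerance = 1e-6)
  }
})

test_that("layer output width is d * |P| with blocks ordered by ascending power", {
  g <- rand_graph(12, 0.3, seed = 3)
  adj <- normalized_adjacency(g)
  Ahat <- dense_norm_adj(g)
  H <- matrix(rnorm(12 * 6), 12, 6)
  Ws <- replicate(4, matrix(rnorm(6 * 5), 6, 5), simplify = FALSE)
  out <- hogc_layer(adj, H, Ws, powers = 0:3)
  expect_equal(dim(out), c(12L, 20L))
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  for (k in 1:4) {
    expect_equal(out[, (k - 1) * 5 + 1:5],
                 elu(dense_power_apply(Ahat, H %*% Ws[[k]], k - 1)),
                 tolerance = 1e-6)
  }
  expect_error(hogc_layer(adj, H, list(matrix(0, 3, 2)), powers = 1L),
               "j = 1")
})

test_that("embeddings have width d*|P| and the reference config gives 128", {
  g <- rand_graph(20, 0.3, seed = 5)
  cfg <- hogcn_config()  # 2 layers, powers 0:3, d = 32
  params <- init_hogcn_params(cfg, 20, seed = 1)
  Z <- encode_nodes(g, params, cfg)
  expect_equal(dim(Z), c(20L, 128L))
  expect_equal(cfg$d_star, 128L)
})

test_that("one-hot lookup encoding equals explicit identity features", {
  g <- rand_graph(30, 0.2, seed = 6)
  cfg <- hogcn_config(powers = 0:2, d = 4, n_layers = 2, dropout = 0)
  params <- init_hogcn_params(cfg, 30, seed = 2)
  expect_equal(encode_nodes(g, params, cfg),
               encode_nodes(g, params, cfg, features = diag(30)),
               tolerance = 1e-12)
})

test_that("encoding is permutation-equivariant", {
  g <- rand_graph(12, 0.35, seed = 7)
  X <- matrix(rnorm(12 * 5), 12, 5)
  cfg <- hogcn_config(powers = 0:3, d = 3, n_layers = 2, dropout = 0)
  params <- init_hogcn_params(cfg, 12, n_features = 5, seed = 3)
  Z <- encode_nodes(g, params, cfg, features = X)
  for (s in 1:20) {
    perm <- sample.int(12)
    gp <- interaction_graph(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                            nodes = g$nodes)
    Zp <- encode_nodes(gp, params, cfg, features = X[order(perm), ])
    expect_equal(Zp[perm, ], Z, tolerance = 1e-8)
  }
})

test_that("bilinear fusion matches the nested-loop oracle in both layouts", {
  set.seed(11)
  ds <- 3L; d_e <- 2L
  W_arr <- array(rnorm(d_e * ds * ds), c(d_e, ds, ds))
  b <- rnorm(d_e)
  z_i <- rnorm(ds); z_j <- rnorm(ds)

  want <- brute_bilinear(z_i, z_j, W_arr, b)
  expect_equal(bilinear_fuse(z_i, z_j, W_arr, b), want, tolerance = 1e-12)
  W_mat <- hognet:::wb_as_matrix(W_arr)
  expect_equal(bilinear_fuse(z_i, z_j, W_mat, b), want, tolerance = 1e-12)
  expect_equal(hognet:::wb_as_array(W_mat, ds), W_arr)

  expect_equal(bilinear_fuse(z_i, z_j, W_arr * 0, b * 0), rep(0, d_e))
  expect_error(bilinear_fuse(rnorm(3), rnorm(4), W_arr, b), "differ")
})

test_that("the reference decoder produces 64-dimensional edge features", {
  cfg <- hogcn_config()
  params <- init_hogcn_params(cfg, 10, seed = 4)
  e <- bilinear_fuse(rnorm(cfg$d_star), rnorm(cfg$d_star), params$Wb,
                     params$b_b)
  expect_length(e, 64L)
})

test_that("the prediction head composes two affine maps, ELU and sigmoid", {
  d_e <- 4L; h <- 3L
  W1 <- matrix(0, d_e, h); b1 <- rep(0, h)
  W2 <- matrix(0, h, 1); b2 <- 0
  expect_equal(predict_edge_probability(rnorm(d_e), W1, b1, W2, b2), 0.5)

  # monotone in the final bias
  ps <- sapply(c(-4, 0, 4, 8), function(bb)
    predict_edge_probability(rep(1, d_e), W1, b1, W2, bb))
  expect_true(all(diff(ps) > 0))

  set.seed(12)
  W1 <- matrix(rnorm(d_e * h), d_e, h); b1 <- rnorm(h)
  W2 <- matrix(rnorm(h), h, 1); b2 <- rnorm(1)
  e <- rnorm(d_e)
  u <- drop(e %*% W1) + b1
  v <- ifelse(u > 0, u, exp(u) - 1)
  want <- 1 / (1 + exp(-(sum(v * W2) + b2)))
  expect_equal(predict_edge_probability(e, W1, b1, W2, b2), want,
               tolerance = 1e-6)
})

test_that("parameter initialization is seeded Xavier-uniform", {
  cfg <- hogcn_config(powers = 0:1, d = 8, n_layers = 1, d_e = 4, h = 4)
  expect_identical(init_hogcn_params(cfg, 50, seed = 9),
                   init_hogcn_params(cfg, 50, seed = 9))

  W <- init_hogcn_params(cfg, 50, seed = 9)$W1_0
  bound <- sqrt(6 / (50 + 8))
  expect_true(all(abs(W) <= bound))

  big <- hogcn_config(powers = 1, d = 100, n_layers = 1)
  Wbig <- init_hogcn_params(big, 100, seed = 10)$W1_1  # 1e4 entries
  expect_equal(stats::var(as.vector(Wbig)), 2 / (100 + 100),
               tolerance = 0.1)
  expect_true(all(init_hogcn_params(cfg, 50, seed = 1)$b_h1 == 0))
})

test_that("predicted probabilities are strictly inside (0, 1)", {
  g <- rand_graph(25, 0.25, seed = 8)
  cfg <- hogcn_config(powers = 0:3, d = 4, d_e = 8, h = 4)
  params <- init_hogcn_params(cfg, 25, seed = 5)
  adj <- normalized_adjacency(g)
  pairs <- t(combn(25, 2))
  p <- hognet:::predict_pairs_prob(adj, NULL, pairs, params, cfg)
  expect_true(all(p > 0 & p < 1))
  expect_length(p, nrow(pairs))
})
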