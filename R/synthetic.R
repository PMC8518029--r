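#' Generate a stochastic block model interaction network
#'
#' Equal-size blocks; each unordered pair is an edge independently with
#' probability `p_in` (same block) or `p_out` (different blocks). Because
#' block co-membership is recoverable from multi-hop neighborhoods, held-out
#' links of such graphs are predictable from topology alone, which is what
#' makes them a useful stand-in for unipartite interaction networks (PPI- or
#' DDI-like) in end-to-end tests.
#'
#' @param n_nodes number of nodes.
#' @param n_blocks number of equal-size blocks (default 2; remainders go to
#'   the leading blocks).
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability (`p_out <= p_in`).
#' @param seed integer seed; identical specs and seeds give identical graphs.
#' @return An `interaction_graph`; block labels are kept in attribute
#'   `"block"`.
#' @export
generate_sbm <- function(n_nodes, n_blocks = 2L, p_in, p_out, seed = 1L) {
  n_nodes <- as.integer(n_nodes); n_blocks <- as.integer(n_blocks)
  if (n_nodes < 2L || n_blocks < 1L) stop("need n_nodes >= 2, n_blocks >= 1")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  block <- sort(rep_len(seq_len(n_blocks), n_nodes))
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  p <- ifelse(block[ut[, 1L]] == block[ut[, 2L]], p_in, p_out)
  keep <- with_seed(seed, stats::runif(nrow(ut)) < p)
  nodes <- sprintf("n%0*d", nchar(n_nodes), seq_len(n_nodes))
  g <- interaction_graph(ut[keep, , drop = FALSE], nodes = nodes)
  attr(g, "block") <- block
  g
}

#' Generate a bipartite latent-factor interaction network
#'
#' Emulates drug-target / gene-disease style networks: each type-A node gets
#' a latent vector `u_a`, each type-B node a `v_b` (r-dimensional standard
#' normal), and the pair `(a, b)` is an edge with probability
#' `sigmoid(u_a' v_b + c)`. The offset `c` is calibrated by bisection so the
#' expected density hits `density`; only cross-type edges exist by
#' construction. Low-rank structure makes held-out links predictable.
#'
#' @param n_a,n_b numbers of type-A and type-B nodes.
#' @param r latent dimension (`>= 1`).
#' @param density target edge density in `(0, 1)` over the `n_a * n_b`
#'   candidate pairs.
#' @param seed integer seed.
#' @return A bipartite `interaction_graph` (node ids `a1..`, `b1..`).
#' @export
generate_bipartite <- function(n_a, n_b, r = 4L, density = 0.05, seed = 1L) {
  n_a <- as.integer(n_a); n_b <- as.integer(n_b); r <- as.integer(r)
  if (r < 1L) stop("latent dimension r must be >= 1")
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  with_seed(seed, {
    U <- matrix(stats::rnorm(n_a * r), n_a, r)
    V <- matrix(stats::rnorm(n_b * r), n_b, r)
    logits <- U %*% t(V)
    lo <- -30; hi <- 30
    f <- function(c) mean(sigmoid(logits + c)) - density
    if (f(lo) > 0 || f(hi) < 0) stop("target density unreachable")
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    p <- sigmoid(logits + (lo + hi) / 2)
    keep <- which(matrix(stats::runif(length(p)), n_a, n_b) < p,
                  arr.ind = TRUE)
    nodes <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
    interaction_graph(
      cbind(keep[, 1L], n_a + keep[, 2L]), nodes = nodes,
      node_type = rep(c("A", "B"), c(n_a, n_b))
    )
  })
}

#' Small hand-coded test graphs
#'
#' Registered fixtures used throughout the unit tests:
#' * `path3` — the path `0-1-2` (3 nodes, 2 edges);
#' * `triangle` — the complete graph on 3 nodes;
#' * `l3_demo` — the 5-node graph `x-a, a-b, b-y, a-c, c-y`, whose `(x, y)`
#'   pair has exactly two degree-normalized length-3 paths;
#' * `bipartite_2x2` — types `{a1, a2}` vs `{b1, b2}` with the single edge
#'   `(a1, b1)`.
#'
#' @param name fixture identifier.
#' @return An `interaction_graph`.
#' @export
toy_fixture <- function(name) {
  fixtures <- list(
    path3 = function() interaction_graph(
      cbind(c("v0", "v1"), c("v1", "v2"))),
    triangle = function() interaction_graph(
      cbind(c("v0", "v0", "v1"), c("v1", "v2", "v2"))),
    l3_demo = function() interaction_graph(
      cbind(c("x", "a", "b", "a", "c"), c("a", "b", "y", "c", "y"))),
    bipartite_2x2 = function() interaction_graph(
      cbind("a1", "b1"), nodes = c("a1", "a2", "b1", "b2"),
      node_type = c("A", "A", "B", "B"))
  )
  if (!name %in% names(fixtures)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "))
  }
  fixtures[[name]]()
}
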