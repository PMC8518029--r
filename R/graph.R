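#' Construct an interaction graph
#'
#' An `interaction_graph` is a simple undirected graph over named biomedical
#' entities (proteins, drugs, genes, diseases, ...). Edges are stored as
#' canonical `(min, max)` 1-based index pairs; self-loops and duplicate edges
#' are rejected. For bipartite networks (drug-target, gene-disease) each node
#' carries a type label `"A"` or `"B"` and every edge must cross types.
#'
#' @param edges two-column matrix or data frame. Character columns are node
#'   identifiers; integer columns are 1-based indices into `nodes`.
#' @param nodes character vector of node identifiers. Required when `edges` is
#'   an index matrix; otherwise inferred in first-appearance order.
#' @param node_type optional character vector (`"A"`/`"B"`, one per node)
#'   marking the two sides of a bipartite network.
#' @param features optional numeric matrix with one row per node. When absent,
#'   models fall back to one-hot (identity) features.
#' @return An object of class `interaction_graph` with elements `nodes`,
#'   `edges` (integer matrix), `node_type` and `features`.
#' @export
interaction_graph <- function(edges, nodes = NULL, node_type = NULL,
                              features = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  if (ncol(edges) < 2L) stop("edges must have at least two columns")
  edges <- edges[, 1:2, drop = FALSE]

  if (is.character(edges)) {
    if (is.null(nodes)) {
      nodes <- unique(as.vector(t(edges)))  # first appearance, row by row
    }
    idx <- matrix(match(as.vector(edges), nodes), ncol = 2L)
    if (anyNA(idx)) {
      bad <- unique(as.vector(edges)[is.na(match(as.vector(edges), nodes))])
      stop("unknown node identifier(s): ", paste(bad, collapse = ", "))
    }
  } else {
    if (is.null(nodes)) stop("nodes must be supplied with an index edge matrix")
    idx <- edges
    storage.mode(idx) <- "integer"
  }
  n <- length(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (nrow(idx) > 0L && (min(idx) < 1L || max(idx) > n)) {
    stop("edge endpoint out of range")
  }
  if (any(idx[, 1L] == idx[, 2L])) stop("self-loops are not allowed")
  idx <- canonical_pairs(idx)
  idx <- idx[!duplicated(pair_key(idx, n)), , drop = FALSE]

  if (!is.null(node_type)) {
    node_type <- as.character(node_type)
    if (length(node_type) != n) stop("node_type must have one entry per node")
    if (!all(node_type %in% c("A", "B"))) stop("node_type entries must be 'A' or 'B'")
    cross <- node_type[idx[, 1L]] != node_type[idx[, 2L]]
    if (!all(cross)) stop("bipartite graph has within-type edge(s)")
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n) stop("features must have one row per node")
    storage.mode(features) <- "double"
  }
  structure(
    list(nodes = nodes, edges = idx, node_type = node_type,
         features = features),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  kind <- if (is.null(x$node_type)) "unipartite" else "bipartite"
  cat(sprintf("Interaction graph (%s): %d nodes, %d edges\n",
              kind, n_nodes(x), n_edges(x)))
  if (!is.null(x$node_type)) {
    cat(sprintf("  type A: %d, type B: %d\n",
                sum(x$node_type == "A"), sum(x$node_type == "B")))
  }
  cat(sprintf("  average degree: %.2f\n", average_degree(x)))
  invisible(x)
}

#' @rdname interaction_graph
#' @param graph an `interaction_graph`.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname interaction_graph
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Average node degree of an interaction network
#'
#' Computed as `2 |E| / |V|`, the mean number of interaction partners per
#' entity; the standard summary used to describe interaction-network density.
#'
#' @param graph an `interaction_graph`.
#' @return A nonnegative number.
#' @export
average_degree <- function(graph) {
  if (n_nodes(graph) < 1L) stop("graph has no nodes")
  2 * n_edges(graph) / n_nodes(graph)
}

#' Read an edge list file
#'
#' Parses a plain-text edge list (`node_a<sep>node_b[<sep>label]`) into an
#' [interaction_graph()]. Lines starting with `#` are skipped. Node order is
#' first appearance in the file, so the adjacency matrix is reproducible
#' byte-for-byte. Duplicate rows (in either orientation) collapse to a single
#' undirected edge; self-loop rows are dropped with a warning.
#'
#' @param path path to the file.
#' @param delimiter field separator, default tab.
#' @param bipartite if `TRUE`, nodes in the first column are typed `"A"` and
#'   nodes in the second `"B"`; a node appearing in both columns is an error.
#' @return An `interaction_graph`.
#' @export
read_edge_list <- function(path, delimiter = "\t", bipartite = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("empty edge list: ", path)
  fields <- strsplit(lines[rows], delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed row at line ", rows[which(nf < 2L)[1L]],
         ": expected at least 2 fields")
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(a == "" | b == "")) {
    stop("malformed row at line ", rows[which(a == "" | b == "")[1L]],
         ": empty identifier")
  }
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped")
  }
  nodes <- unique(as.vector(rbind(a, b)))  # first appearance
  a <- a[!self]; b <- b[!self]
  node_type <- NULL
  if (bipartite) {
    in_a <- nodes %in% a
    in_b <- nodes %in% b
    both <- in_a & in_b
    if (any(both)) {
      stop("bipartite mode: node(s) appear in both columns: ",
           paste(utils::head(nodes[both], 5L), collapse = ", "))
    }
    node_type <- ifelse(in_a, "A", "B")
  }
  interaction_graph(cbind(a, b), nodes = nodes, node_type = node_type)
}

#' Write an edge list file
#'
#' Inverse of [read_edge_list()]: one `node_a<sep>node_b` row per undirected
#' edge, in canonical order.
#'
#' @param graph an `interaction_graph`.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, delimiter = "\t") {
  a <- graph$nodes[graph$edges[, 1L]]
  b <- graph$nodes[graph$edges[, 2L]]
  writeLines(paste(a, b, sep = delimiter), path)
  invisible(path)
}

# Resolve node identifiers (character) or indices to validated integer indices.
resolve_nodes <- function(graph, x) {
  if (is.character(x)) {
    idx <- match(x, graph$nodes)
    if (anyNA(idx)) stop("unknown node identifier(s): ",
                         paste(unique(x[is.na(idx)]), collapse = ", "))
    return(idx)
  }
  idx <- as.integer(x)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_nodes(graph))) {
    stop("node index out of range")
  }
  idx
}

# Resolve a 2-column pair specification (ids or indices) to canonical indices.
resolve_pairs <- function(graph, pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  idx <- cbind(resolve_nodes(graph, pairs[, 1L]),
               resolve_nodes(graph, pairs[, 2L]))
  if (any(idx[, 1L] == idx[, 2L])) stop("self-pairs are not allowed")
  canonical_pairs(idx)
}

#' Binary adjacency matrix of a graph
#'
#' Sparse symmetric 0/1 adjacency without self-loops, the `A` used by the
#' path-count heuristics.
#'
#' @param graph an `interaction_graph`.
#' @return A sparse symmetric `Matrix`.
#' @export
adjacency_matrix <- function(graph) {
  n <- n_nodes(graph)
  e <- graph$edges
  Matrix::sparseMatrix(
    i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
    x = 1, dims = c(n, n), dimnames = list(graph$nodes, graph$nodes)
  )
}

#' Symmetrically normalized adjacency with self-connections
#'
#' Builds `A_hat = D^(-1/2) (A + I) D^(-1/2)`, the propagation operator of
#' graph convolutional layers, where `D` counts degrees after adding the
#' self-loop. Entry `(i, j)` equals `1 / sqrt(d_i d_j)` for every edge and
#' self-loop and 0 elsewhere; an isolated node gets `A_hat[i, i] = 1`.
#'
#' @param graph an `interaction_graph`.
#' @return An object of class `normalized_adjacency` with elements `matrix`
#'   (sparse symmetric) and `degrees` (degree including the self-loop).
#' @export
normalized_adjacency <- function(graph) {
  n <- n_nodes(graph)
  if (n < 1L) stop("graph has no nodes")
  A <- adjacency_matrix(graph)
  d <- Matrix::rowSums(A) + 1
  dinv <- 1 / sqrt(d)
  Ahat <- Matrix::Diagonal(x = dinv) %*% (A + Matrix::Diagonal(n)) %*%
    Matrix::Diagonal(x = dinv)
  structure(
    list(matrix = methods::as(Ahat, "generalMatrix"), degrees = d),
    class = "normalized_adjacency"
  )
}

#' @export
print.normalized_adjacency <- function(x, ...) {
  cat(sprintf("Normalized adjacency: %d x %d, %d nonzeros\n",
              nrow(x$matrix), ncol(x$matrix), Matrix::nnzero(x$matrix)))
  invisible(x)
}

# Accept either a normalized_adjacency or a bare sparse matrix.
as_adj_matrix <- function(adj) {
  if (inherits(adj, "normalized_adjacency")) adj$matrix else adj
}
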