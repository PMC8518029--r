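#' Ratio split of positive edges
#'
#' Shuffles the edge set with a seeded generator and partitions it into
#' train/validation/test subsets. Sizes are `floor(r_train m)`,
#' `floor(r_val m)` and the remainder, so the three parts always conserve the
#' edge count. The canonical protocol for interaction prediction uses
#' `c(0.7, 0.1, 0.2)`.
#'
#' @param graph an `interaction_graph`.
#' @param ratios three positive proportions summing to 1.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return An object of class `edge_split`: integer edge matrices `train`,
#'   `validation`, `test`, plus `ratios` and `seed`.
#' @export
split_edges <- function(graph, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be three positive proportions")
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  m <- n_edges(graph)
  n_train <- floor(ratios[1L] * m)
  n_val <- floor(ratios[2L] * m)
  n_test <- m - n_train - n_val
  if (n_train < 1L || n_val < 1L || n_test < 1L) {
    stop("graph too small for the requested split; use a larger graph")
  }
  ord <- with_seed(seed, sample.int(m))
  e <- graph$edges[ord, , drop = FALSE]
  structure(
    list(
      train = e[seq_len(n_train), , drop = FALSE],
      validation = e[n_train + seq_len(n_val), , drop = FALSE],
      test = e[n_train + n_val + seq_len(n_test), , drop = FALSE],
      ratios = ratios, seed = as.integer(seed)
    ),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("Edge split (%s, seed %d): train %d / validation %d / test %d\n",
              paste(x$ratios, collapse = ":"), x$seed,
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Persist an edge split as three edge-list files plus a JSON sidecar
#'
#' @param graph the `interaction_graph` the split indexes into.
#' @param split an `edge_split`.
#' @param dir output directory (created if missing).
#' @param delimiter field separator for the edge-list files.
#' @return `dir`, invisibly.
#' @export
write_split <- function(graph, split, dir, delimiter = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "validation", "test")) {
    e <- split[[part]]
    writeLines(paste(graph$nodes[e[, 1L]], graph$nodes[e[, 2L]],
                     sep = delimiter),
               file.path(dir, paste0(part, ".tsv")))
  }
  jsonlite::write_json(
    list(ratios = split$ratios, seed = split$seed,
         sizes = list(train = nrow(split$train),
                      validation = nrow(split$validation),
                      test = nrow(split$test))),
    file.path(dir, "split.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Sample negative (non-interacting) node pairs
#'
#' Draws `count` distinct node pairs from the complement of the full positive
#' edge set — all of train, validation and test positives are excluded, so
#' negatives can never leak label information across splits. Self-pairs are
#' never drawn. In bipartite mode only cross-type pairs are candidates,
#' because same-type pairs are structurally impossible positives in
#' drug-target or gene-disease data.
#'
#' @param graph an `interaction_graph`.
#' @param count number of negatives to draw.
#' @param seed integer seed; identical seeds give identical samples.
#' @param bipartite restrict candidates to cross-type pairs. Defaults to
#'   `TRUE` when the graph carries node types.
#' @return A `labeled_edges` object: matrix `pairs` and integer `labels`
#'   (all 0).
#' @export
sample_negatives <- function(graph, count, seed = 1L,
                             bipartite = !is.null(graph$node_type)) {
  n <- n_nodes(graph)
  count <- as.integer(count)
  if (count < 1L) stop("count must be positive")
  if (bipartite && is.null(graph$node_type)) {
    stop("bipartite negative sampling requires node types")
  }
  pos_keys <- pair_key(graph$edges, n)
  if (bipartite) {
    na_ <- sum(graph$node_type == "A")
    nb_ <- sum(graph$node_type == "B")
    total <- as.numeric(na_) * nb_
  } else {
    total <- as.numeric(n) * (n - 1) / 2
  }
  avail <- total - length(pos_keys)
  if (count > avail) {
    stop("complement exhausted: only ", avail,
         " candidate non-edges available, requested ", count)
  }

  draw <- with_seed(seed, {
    if (total <= 2e5) {
      # Small pair universe: enumerate the complement and sample exactly.
      cand <- all_candidate_pairs(graph, bipartite)
      cand <- cand[!(pair_key(cand, n) %in% pos_keys), , drop = FALSE]
      cand[sample.int(nrow(cand), count), , drop = FALSE]
    } else {
      rejection_sample_negatives(graph, count, bipartite, pos_keys)
    }
  })
  labeled_edges(draw, rep(0L, count))
}

# All unordered candidate pairs (cross-type only in bipartite mode).
all_candidate_pairs <- function(graph, bipartite) {
  n <- n_nodes(graph)
  if (bipartite) {
    ia <- which(graph$node_type == "A")
    ib <- which(graph$node_type == "B")
    canonical_pairs(cbind(rep(ia, each = length(ib)), rep(ib, length(ia))))
  } else {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    canonical_pairs(idx)
  }
}

rejection_sample_negatives <- function(graph, count, bipartite, pos_keys) {
  n <- n_nodes(graph)
  got <- matrix(integer(), ncol = 2L)
  seen <- numeric()
  while (nrow(got) < count) {
    k <- 2L * (count - nrow(got)) + 16L
    if (bipartite) {
      ia <- which(graph$node_type == "A")
      ib <- which(graph$node_type == "B")
      cand <- cbind(sample(ia, k, replace = TRUE), sample(ib, k, replace = TRUE))
    } else {
      cand <- cbind(sample.int(n, k, replace = TRUE),
                    sample.int(n, k, replace = TRUE))
      cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
    }
    cand <- canonical_pairs(cand)
    keys <- pair_key(cand, n)
    ok <- !(keys %in% pos_keys) & !(keys %in% seen) & !duplicated(keys)
    cand <- cand[ok, , drop = FALSE]
    seen <- c(seen, keys[ok])
    got <- rbind(got, cand)
  }
  got[seq_len(count), , drop = FALSE]
}

#' Node pairs with binary interaction labels
#'
#' Container pairing a list of canonical node-index pairs with 0/1 labels,
#' used for training batches and evaluation sets.
#'
#' @param pairs two-column integer matrix of node indices.
#' @param labels binary vector, one entry per pair.
#' @return An object of class `labeled_edges`.
#' @export
labeled_edges <- function(pairs, labels) {
  pairs <- canonical_pairs(pairs)
  labels <- as.integer(labels)
  if (nrow(pairs) != length(labels)) stop("pairs and labels lengths differ")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(list(pairs = pairs, labels = labels), class = "labeled_edges")
}

#' @export
print.labeled_edges <- function(x, ...) {
  cat(sprintf("Labeled edge set: %d pairs (%d positive, %d negative)\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

# Graph restricted to the training edges (same nodes/types/features), used
# as the message-passing graph so held-out edges stay invisible.
training_graph <- function(graph, split) {
  interaction_graph(split$train, nodes = graph$nodes,
                    node_type = graph$node_type, features = graph$features)
}

# Positives of one split part + freshly sampled negatives of equal count.
balanced_labeled_set <- function(graph, pos_pairs, seed, bipartite) {
  k <- nrow(pos_pairs)
  neg <- sample_negatives(graph, k, seed = seed, bipartite = bipartite)
  labeled_edges(rbind(pos_pairs, neg$pairs), c(rep(1L, k), rep(0L, k)))
}
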