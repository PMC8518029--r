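edge_file <- function(rows, sep = "\t") {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(vapply(rows, paste, "", collapse = sep), f)
  f
}

test_that("edge list reading collapses undirected duplicates and keeps file order", {
  f <- edge_file(list(c("a", "b"), c("b", "a"), c("a", "b")))
  g <- read_edge_list(f)
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_edges(g), 1L)
  expect_equal(g$nodes, c("a", "b"))

  f2 <- edge_file(list(c("a", "b"), c("b", "c"), c("c", "d"),
                       c("d", "e"), c("a", "b")))
  g2 <- read_edge_list(f2)
  expect_equal(n_nodes(g2), 5L)
  expect_equal(n_edges(g2), 4L)
  expect_equal(g2$nodes, c("a", "b", "c", "d", "e"))
})

test_that("self-loop rows are dropped with a warning; comments skipped; csv works", {
  f <- edge_file(list(c("a", "a")))
  expect_warning(g <- read_edge_list(f), "self-loop")
  expect_equal(n_nodes(g), 1L)
  expect_equal(n_edges(g), 0L)

  f2 <- edge_file(list("# header comment", c("x", "y")), sep = ",")
  # comment row has one field under ",", so it must be skipped before parsing
  g2 <- read_edge_list(f2, delimiter = ",")
  expect_equal(n_edges(g2), 1L)
})

test_that("malformed and empty files give informative errors", {
  f <- edge_file(list(c("a", "b"), "lonely"))
  expect_error(read_edge_list(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# only comments"), f2)
  expect_error(read_edge_list(f2), "empty")
  expect_error(read_edge_list(file.path(tempdir(), "no-such-file.tsv")),
               "not found")
})

test_that("bipartite reading types columns and rejects side-switching nodes", {
  f <- edge_file(list(c("d1", "t1"), c("d2", "t1")))
  g <- read_edge_list(f, bipartite = TRUE)
  expect_equal(g$node_type, c("A", "B", "A"))
  f2 <- edge_file(list(c("d1", "t1"), c("t1", "d1")))
  expect_error(read_edge_list(f2, bipartite = TRUE), "both columns")
})

test_that("edge lists round-trip through write_edge_list", {
  g <- generate_sbm(20, 2, 0.4, 0.1, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  expect_equal(sort(g2$nodes), sort(g$nodes))
  expect_equal(n_edges(g2), n_edges(g))
})

test_that("normalized adjacency matches the closed form", {
  g1 <- interaction_graph(matrix(character(), ncol = 2), nodes = "solo")
  expect_equal(unname(as.matrix(normalized_adjacency(g1)$matrix)),
               matrix(1))

  g2 <- interaction_graph(cbind("u", "v"))
  expect_equal(unname(as.matrix(normalized_adjacency(g2)$matrix)),
               matrix(0.5, 2, 2))

  p3 <- toy_fixture("path3")
  m <- unname(as.matrix(normalized_adjacency(p3)$matrix))
  expect_equal(m[1, 2], 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(m[2, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(m[1, 3], 0)
  expect_equal(m, dense_norm_adj(p3), tolerance = 1e-12)
})

test_that("normalized adjacency is symmetric and ring row sums equal one", {
  for (s in 1:5) {
    g <- rand_graph(25, 0.15, seed = s)
    m <- as.matrix(normalized_adjacency(g)$matrix)
    expect_equal(max(abs(m - t(m))), 0)
  }
  # ring = 2-regular graph; with self-loops every degree is 3 and each row of
  # the normalized operator sums to exactly 1
  n <- 12
  ring <- interaction_graph(cbind(1:n, c(2:n, 1L)),
                            nodes = sprintf("r%d", 1:n))
  expect_equal(unname(Matrix::rowSums(normalized_adjacency(ring)$matrix)),
               rep(1, n), tolerance = 1e-12)
})

test_that("edge splits have floor/floor/remainder sizes and conserve edges", {
  g20 <- lattice_graph(10, 20)
  s <- split_edges(g20, c(0.7, 0.1, 0.2), seed = 1)
  expect_equal(c(nrow(s$train), nrow(s$validation), nrow(s$test)),
               c(14L, 2L, 4L))

  g10 <- lattice_graph(6, 10)
  s10 <- split_edges(g10, c(0.7, 0.1, 0.2), seed = 1)
  expect_equal(c(nrow(s10$train), nrow(s10$validation), nrow(s10$test)),
               c(7L, 1L, 2L))

  # conservation and disjointness across ratios and seeds
  g <- rand_graph(30, 0.2, seed = 2)
  for (ratios in list(c(0.7, 0.1, 0.2), c(0.5, 0.25, 0.25), c(1, 1, 1) / 3)) {
    for (seed in 1:3) {
      sp <- split_edges(g, ratios, seed = seed)
      all_edges <- rbind(sp$train, sp$validation, sp$test)
      expect_equal(nrow(all_edges), n_edges(g))
      keys <- (all_edges[, 1] - 1) * n_nodes(g) + all_edges[, 2]
      expect_false(any(duplicated(keys)))
      expect_setequal(keys, (g$edges[, 1] - 1) * n_nodes(g) + g$edges[, 2])
    }
  }
})

test_that("edge splits are deterministic in the seed and validate inputs", {
  g <- rand_graph(20, 0.3, seed = 7)
  expect_identical(split_edges(g, seed = 42), split_edges(g, seed = 42))
  expect_false(identical(split_edges(g, seed = 1)$train,
                         split_edges(g, seed = 2)$train))
  expect_error(split_edges(g, c(0.5, 0.5, 0.1)), "sum to 1")
  tiny <- toy_fixture("path3")
  expect_error(split_edges(tiny), "larger graph")
})

test_that("negative sampling enumerates the complement exactly on small graphs", {
  expect_error(sample_negatives(toy_fixture("triangle"), 1),
               "complement exhausted")

  g <- interaction_graph(rbind(c(1L, 2L), c(3L, 4L)),
                         nodes = c("a", "b", "c", "d"))
  neg <- sample_negatives(g, 4, seed = 1)
  expect_equal(sort(paste(neg$pairs[, 1], neg$pairs[, 2])),
               c("1 3", "1 4", "2 3", "2 4"))
  expect_true(all(neg$labels == 0L))

  b <- toy_fixture("bipartite_2x2")
  nb <- sample_negatives(b, 3, seed = 1)
  tt <- cbind(b$node_type[nb$pairs[, 1]], b$node_type[nb$pairs[, 2]])
  expect_true(all(tt[, 1] != tt[, 2]))
  expect_equal(nrow(nb$pairs), 3L)
  expect_error(sample_negatives(b, 4), "complement exhausted")
})

test_that("sampled negatives never intersect positives across many seeds", {
  for (seed in 1:100) {
    g <- rand_graph(30, 0.2, seed = seed)
    neg <- sample_negatives(g, 25, seed = seed + 1000L)
    expect_length(
      intersect(hognet:::pair_key(neg$pairs, 30),
                hognet:::pair_key(g$edges, 30)),
      0
    )
    expect_false(any(neg$pairs[, 1] == neg$pairs[, 2]))
    expect_false(any(duplicated(hognet:::pair_key(neg$pairs, 30))))
  }
  g <- rand_graph(30, 0.2, seed = 3)
  expect_identical(sample_negatives(g, 10, seed = 9),
                   sample_negatives(g, 10, seed = 9))
})

test_that("average degree is 2|E|/|V|", {
  expect_equal(average_degree(interaction_graph(cbind("u", "v"))), 1.0)
  g <- lattice_graph(9, 18)
  expect_equal(average_degree(g), 4.0)
})
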