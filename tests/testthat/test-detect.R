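# two disconnected cliques as a weighted hypergraph
two_cliques <- function(k) {
  H <- matrix(0, 2 * k, 2 * k)
  H[1:k, 1:k] <- 1
  H[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(H) <- 0
  H
}

test_that("modularity matches closed forms and a brute-force oracle", {
  H <- two_cliques(4)
  labs <- rep(1:2, each = 4)
  expect_equal(modularity_q(H, labs), 0.5, tolerance = 1e-12)
  expect_equal(modularity_q(H, rep(1, 8)), 0, tolerance = 1e-12)

  set.seed(8)
  Hr <- matrix(runif(64), 8, 8)
  Hr <- (Hr + t(Hr)) / 2
  diag(Hr) <- 0
  for (gamma in c(0.5, 1, 1.7)) {
    labs <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(Hr, labs, gamma),
                 oracle_modularity(Hr, labs, gamma), tolerance = 1e-12)
    # independent cross-check via igraph
    g <- igraph::graph_from_adjacency_matrix(Hr, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(modularity_q(Hr, labs, gamma),
                 igraph::modularity(g, labs, weights = igraph::E(g)$weight,
                                    resolution = gamma),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "all-zero")
})

test_that("Louvain separates disconnected cliques and is reproducible", {
  H <- two_cliques(5)
  part <- louvain_partition(H, n_restarts = 5, seed = 1)
  expect_equal(length(unique(part$labels)), 2L)
  expect_equal(length(unique(part$labels[1:5])), 1L)
  expect_equal(length(unique(part$labels[6:10])), 1L)
  # Q at least that of the trivial one-community partition
  expect_gte(part$Q, modularity_q(H, rep(1, 10)))
  part2 <- louvain_partition(H, n_restarts = 5, seed = 1)
  expect_identical(part$labels, part2$labels)
})

test_that("planted blocks in a synthetic hypergraph are recovered", {
  # 4 blocks of 25 nodes, within-block weight 0.9, between 0
  H <- matrix(0, 100, 100)
  truth <- rep(1:4, each = 25)
  for (b in 1:4) H[truth == b, truth == b] <- 0.9
  diag(H) <- 0
  aris <- vapply(1:20, function(s) {
    part <- louvain_partition(H, n_restarts = 5, seed = s)
    ari(part$labels, truth)
  }, 0)
  expect_gte(min(aris), 0.9)
})

test_that("partition is equivariant under node permutation", {
  H <- two_cliques(4) + 0.1
  diag(H) <- 0
  set.seed(9)
  perm <- sample(8)
  p1 <- louvain_partition(H, n_restarts = 10, seed = 2)
  p2 <- louvain_partition(H[perm, perm], n_restarts = 10, seed = 2)
  expect_equal(ari(p1$labels[perm], p2$labels), 1)
})

test_that("hyperedge extraction filters size and respects the partition", {
  part <- structure(list(labels = c(1L, 1L, 1L, 2L, 3L),
                         edges = 1:5,
                         pairs = cbind(i = c(1, 1, 1, 2, 3),
                                       j = c(2, 3, 4, 5, 6))),
                    class = "edge_partition")
  he <- extract_hyperedges(part, min_size = 2)
  expect_length(he, 1L)
  expect_equal(he[[1]]$members, 1:3)
  expect_equal(he[[1]]$nodes, 1:4)
  expect_length(extract_hyperedges(part, min_size = 10), 0L)
})

test_that("cohesive-core pruning strips weakly attached members only", {
  # 6-member strong core plus 3 hangers-on correlated ~0.15 with everyone
  H <- matrix(0, 9, 9)
  H[1:6, 1:6] <- 0.9
  H[7:9, 1:9] <- H[1:9, 7:9] <- 0.15
  diag(H) <- 0
  part <- structure(list(labels = rep(1L, 9), edges = 1:9,
                         pairs = cbind(i = 1:9, j = 2:10)),
                    class = "edge_partition")
  he <- extract_hyperedges(part, H = structure(H, class = "hypergraph"))
  expect_equal(he[[1]]$members, 1:6)
  # without H the community is passed through whole
  he2 <- extract_hyperedges(part)
  expect_equal(he2[[1]]$members, 1:9)
})

test_that("hyperedges are disjoint subsets of the retained edges", {
  coh <- generate_cohort(default_cohort_spec(n_subjects = 60, seed = 12))
  W <- extract_edge_vectors(coh$tensor)
  H <- build_hypergraph(W)
  part <- louvain_partition(H, n_restarts = 10, seed = 12)
  he <- extract_hyperedges(part, H = H)
  members <- unlist(lapply(he, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  expect_true(all(unlist(lapply(he, `[[`, "edges")) %in% attr(W, "edges")))
})
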