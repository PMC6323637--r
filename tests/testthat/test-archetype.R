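test_that("induced node graphs mirror the member edges exactly", {
  g <- induced_node_graph(cbind(i = c(1, 1, 1), j = c(2, 3, 4)))
  expect_equal(g$nodes, 1:4)
  expect_equal(rowSums(g$adjacency), c(3, 1, 1, 1))

  k4 <- induced_node_graph(clique_pairs(4))
  expect_equal(k4$adjacency, 1L - diag(4L), ignore_attr = TRUE)

  # node count equals the endpoint union under random edge sets
  set.seed(10)
  for (r in 1:10) {
    pr <- cbind(i = sample(20, 8), j = 21 + sample(10, 8, replace = TRUE))
    gg <- induced_node_graph(pr)
    expect_equal(length(gg$nodes), length(unique(as.integer(pr))))
    expect_equal(sum(gg$adjacency) / 2, nrow(unique(pr)))
  }
})

test_that("max-cut bipartivity matches closed forms", {
  # trees/bipartite graphs cut everything
  k18 <- best_bipartition(induced_node_graph(complete_bipartite_pairs(1, 8)))
  expect_equal(k18$b, 1)
  expect_true(k18$is_bipartite)
  expect_setequal(k18$part1, 1L)  # the balanced tie-break keeps the core alone

  k6 <- best_bipartition(induced_node_graph(clique_pairs(6)))
  expect_equal(k6$cut, 9L)
  expect_equal(k6$b, 0.6)
  expect_false(k6$is_bipartite)

  c5 <- best_bipartition(induced_node_graph(cycle_pairs(5)))
  expect_equal(c5$cut, 4L)
  expect_equal(c5$b, 0.8)
  expect_false(c5$is_bipartite)
})

test_that("exact max cut agrees with subset-enumeration oracle", {
  set.seed(11)
  for (r in 1:8) {
    n <- sample(5:12, 1)
    B <- matrix(0L, n, n)
    for (k in seq_len(round(n * 1.5))) {
      ij <- sample(n, 2)
      B[ij[1], ij[2]] <- B[ij[2], ij[1]] <- 1L
    }
    if (sum(B) == 0) next
    g <- structure(list(adjacency = B, nodes = seq_len(n),
                        n_edges = sum(B) / 2), class = "node_graph")
    expect_equal(best_bipartition(g)$cut, oracle_maxcut(B))
  }
})

test_that("local search matches exact enumeration above the cutoff", {
  set.seed(12)
  pr <- complete_bipartite_pairs(10, 14)  # 24 nodes, known max cut = 140
  g <- induced_node_graph(pr)
  bp <- best_bipartition(g, exact_limit = 20L)
  expect_equal(bp$cut, 140L)
  expect_equal(bp$b, 1)
})

test_that("classifier applies the two-step star/bridge/cluster rule", {
  lab <- function(pr, ...) classify_hyperedge(induced_node_graph(pr), ...)$label
  expect_equal(lab(complete_bipartite_pairs(3, 10)), "star")
  expect_equal(lab(complete_bipartite_pairs(4, 10)), "bridge")
  expect_equal(lab(clique_pairs(6)), "cluster")
  # single edge: bipartite with smaller part of one node -> star
  one <- classify_hyperedge(induced_node_graph(cbind(i = 1, j = 2)))
  expect_equal(one$label, "star")
  expect_length(one$core, 1L)
  # equal parts: K_{5,5} -> bridge, K_{3,3} -> star
  expect_equal(lab(complete_bipartite_pairs(5, 5)), "bridge")
  expect_equal(lab(complete_bipartite_pairs(3, 3)), "star")
})

test_that("classification is invariant under node relabeling", {
  set.seed(13)
  pr <- complete_bipartite_pairs(2, 7)
  base <- classify_hyperedge(induced_node_graph(pr))
  for (r in 1:5) {
    perm <- sample(9)
    pr2 <- cbind(i = pmin(perm[pr[, 1]], perm[pr[, 2]]),
                 j = pmax(perm[pr[, 1]], perm[pr[, 2]]))
    a <- classify_hyperedge(induced_node_graph(pr2))
    expect_equal(a$label, base$label)
    expect_setequal(a$core, perm[1:2])
  }
})

test_that("two-colorable graphs always reach b = 1 and are never clusters", {
  set.seed(14)
  for (r in 1:10) {
    m <- sample(1:6, 1)
    n <- sample(4:8, 1)
    pr <- complete_bipartite_pairs(m, n)
    keep <- sample(nrow(pr), max(m + n - 1, round(nrow(pr) * 0.7)))
    pr <- pr[keep, , drop = FALSE]
    g <- induced_node_graph(pr)
    a <- classify_hyperedge(g)
    expect_equal(a$bipartition$b, 1)
    expect_true(a$label != "cluster")
  }
})

test_that("nodal scores follow the core/degree definitions", {
  he <- list(
    structure(list(id = 1L, members = 1:5, edges = 1:5,
                   pairs = complete_bipartite_pairs(1, 5),
                   nodes = 1:6, size = 5L), class = "hyperedge"),
    structure(list(id = 2L, members = 6:11, edges = 6:11,
                   pairs = cbind(i = rep(7:8, each = 3), j = rep(10:12, 2)),
                   nodes = c(7, 8, 10, 11, 12), size = 6L), class = "hyperedge"),
    structure(list(id = 3L, members = 12:14, edges = 12:14,
                   pairs = clique_pairs(3) + 12L,
                   nodes = 13:15, size = 3L), class = "hyperedge")
  )
  # assign labels directly: scores depend on the label, not on how the
  # classifier would read these small graphs (K_{2,3} itself would be a star)
  arch <- list(list(label = "star", core = 1L),
               list(label = "bridge", core = integer(0)),
               list(label = "cluster", core = integer(0)))
  sc <- nodal_scores(he, arch, n_regions = 15)
  expect_equal(sc$scores$star_score, c(1, rep(0, 14)))
  # K_{2,3} bridge: sides get degree 3 and 2
  expect_equal(sc$scores$bridge_score[c(7, 8)], c(3, 3))
  expect_equal(sc$scores$bridge_score[10:12], c(2, 2, 2))
  # triangle cluster on 13:15
  expect_equal(sc$scores$cluster_score[13:15], c(2, 2, 2))
  # handshake identities
  expect_equal(sum(sc$scores$bridge_score), 2 * 6)
  expect_equal(sum(sc$scores$cluster_score), 2 * 3)
  # brute-force rescan of degrees agrees
  deg <- tabulate(as.integer(he[[2]]$pairs), nbins = 15)
  expect_equal(sc$scores$bridge_score, deg)

  # per-system normalization
  sys <- rep(c("A", "B", "C"), each = 5)
  sc2 <- nodal_scores(he, arch, 15, system_map = sys)
  expect_equal(sc2$system_percent$star_pct, c(100 / 5, 0, 0))
  expect_equal(sum(sc2$system_percent$cluster_pct * 5 / 100), 1)
})
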