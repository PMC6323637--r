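#' Binary node graph induced by a hyperedge
#'
#' Collects the brain regions touched by at least one member edge of the
#' hyperedge and builds the binary adjacency matrix over those regions, with
#' a 1 wherever the connecting edge is a member of the hyperedge.
#'
#' @param h A `hyperedge` (from [extract_hyperedges()]) or any two-column
#'   matrix of region pairs.
#' @return An object of class `node_graph`: list with `adjacency` (binary
#'   symmetric matrix over the induced nodes), `nodes` (region indices, in
#'   increasing order, mapping matrix rows to regions), and `n_edges`.
#' @export
induced_node_graph <- function(h) {
  pairs <- if (inherits(h, "hyperedge")) h$pairs else h
  if (is.null(pairs) || nrow(pairs) < 1L) stop("hyperedge has no member edges")
  nodes <- sort(unique(as.integer(pairs)))
  n <- length(nodes)
  B <- matrix(0L, n, n)
  ri <- match(pairs[, 1L], nodes)
  rj <- match(pairs[, 2L], nodes)
  B[cbind(ri, rj)] <- 1L
  B[cbind(rj, ri)] <- 1L
  structure(list(adjacency = B, nodes = nodes, n_edges = nrow(pairs)),
            class = "node_graph")
}

# exact max cut by enumerating 2^(n-1) bipartitions (node n pinned to part
# one to kill the mirror symmetry); vectorized over bitmask chunks
maxcut_exact <- function(B) {
  n <- nrow(B)
  ei <- row(B)[upper.tri(B) & B != 0]
  ej <- col(B)[upper.tri(B) & B != 0]
  n_masks <- bitwShiftL(1L, n - 1L)
  best_cut <- -1L
  best_mask <- 0L
  best_imbalance <- n + 1L
  chunk <- 262144L
  for (start in seq.int(0L, n_masks - 1L, by = chunk)) {
    masks <- start:min(start + chunk - 1L, n_masks - 1L)
    bits <- matrix(0L, length(masks), n)  # part membership per node
    for (b in seq_len(n - 1L)) {
      bits[, b] <- bitwAnd(bitwShiftR(masks, b - 1L), 1L)
    }
    cuts <- integer(length(masks))
    for (e in seq_along(ei)) {
      cuts <- cuts + (bits[, ei[e]] != bits[, ej[e]])
    }
    sizes <- rowSums(bits)                 # size of part 1 (node n in part 0)
    imbalance <- abs(n - 2L * sizes)
    # maximize cut; break ties toward balance, then the smallest mask
    better <- cuts > best_cut |
      (cuts == best_cut & imbalance < best_imbalance)
    if (any(better)) {
      cand <- which(better)
      o <- cand[order(-cuts[cand], imbalance[cand], masks[cand])[1L]]
      best_cut <- cuts[o]
      best_mask <- masks[o]
      best_imbalance <- imbalance[o]
    }
  }
  part1 <- which(bitwAnd(bitwShiftR(best_mask, 0:(n - 1L)), 1L) == 1L)
  list(cut = best_cut, part1 = part1)
}

# greedy single-node-flip local search from a starting assignment
maxcut_local <- function(B, assign) {
  n <- nrow(B)
  repeat {
    # gain of flipping node v: (same-side degree) - (cross-side degree)
    same <- vapply(seq_len(n), function(v) sum(B[v, assign == assign[v]]), 0)
    cross <- rowSums(B) - same
    gains <- same - cross
    v <- which.max(gains)
    if (gains[v] <= 0) break
    assign[v] <- 1L - assign[v]
  }
  cut <- sum(B[assign == 1L, assign == 0L, drop = FALSE])
  list(cut = cut, assign = assign)
}

#' Best bipartition (maximum cut) of a hyperedge's node graph
#'
#' Splits the induced node graph into two parts so as to maximize the number
#' of edges crossing the split. The bipartivity `b` — the fraction of edges
#' in the cut — equals 1 exactly when the graph is two-colorable; near-1
#' values indicate an approximately bipartite structure. Graphs with up to
#' `exact_limit` nodes are solved exactly by enumeration; larger graphs use
#' a spectral-initialized greedy local search with random restarts.
#'
#' @param g A `node_graph` from [induced_node_graph()].
#' @param tau Bipartivity threshold above which the graph is called
#'   bipartite-like (default 0.9).
#' @param exact_limit Largest node count solved by exhaustive enumeration
#'   (default 20).
#' @param n_restarts Random restarts for the local search above the limit.
#' @param seed Seed for the restart randomization.
#'
#' @return A list of class `bipartition` with `part1`, `part2` (region
#'   indices), `cut` (edges crossing), `n_edges`, `b` (bipartivity), and
#'   `is_bipartite` (`b >= tau`).
#' @export
best_bipartition <- function(g, tau = 0.9, exact_limit = 20L,
                             n_restarts = 50L, seed = 1L) {
  stopifnot(inherits(g, "node_graph"))
  B <- g$adjacency
  n <- nrow(B)
  if (n < 2L) stop("a bipartition needs at least 2 nodes")
  if (n <= exact_limit) {
    res <- maxcut_exact(B)
    in1 <- seq_len(n) %in% res$part1
    cut <- res$cut
  } else {
    # spectral start: most negative eigenvector of the adjacency separates
    # the parts of a near-bipartite graph
    ev <- eigen(B, symmetric = TRUE)
    assign0 <- as.integer(ev$vectors[, n] > 0)
    best <- maxcut_local(B, assign0)
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      cand <- maxcut_local(B, sample(0:1, n, replace = TRUE))
      take <- cand$cut > best$cut ||
        (cand$cut == best$cut &&
           abs(n - 2 * sum(cand$assign)) < abs(n - 2 * sum(best$assign)))
      if (take) best <- cand
    }
    in1 <- best$assign == 1L
    cut <- best$cut
  }
  total <- g$n_edges
  b <- cut / total
  structure(
    list(part1 = g$nodes[in1], part2 = g$nodes[!in1],
         cut = as.integer(cut), n_edges = total,
         b = b, is_bipartite = b >= tau),
    class = "bipartition"
  )
}

#' Classify a hyperedge's node graph as cluster, star, or bridge
#'
#' Two-step taxonomy: (i) if the node graph cannot be split into a
#' near-bipartite structure (bipartivity below `tau`), it is a *cluster* —
#' edges run both within and between node sets; (ii) otherwise the smaller
#' part of the best bipartition is inspected: fewer than 4 nodes makes the
#' hyperedge a *star* whose core is that smaller part, and 4 or more makes
#' it a *bridge* linking two disjoint node sets.
#'
#' @param g A `node_graph`, or a `hyperedge` (converted internally).
#' @param tau Bipartivity threshold (default 0.9).
#' @param ... Passed to [best_bipartition()].
#'
#' @return A list of class `archetype` with `label` (one of `"cluster"`,
#'   `"star"`, `"bridge"`), `core` (star core regions, empty otherwise),
#'   and the underlying `bipartition`.
#' @export
classify_hyperedge <- function(g, tau = 0.9, ...) {
  if (inherits(g, "hyperedge")) g <- induced_node_graph(g)
  stopifnot(inherits(g, "node_graph"))
  bp <- best_bipartition(g, tau = tau, ...)
  if (!bp$is_bipartite) {
    label <- "cluster"
    core <- integer(0)
  } else {
    sizes <- c(length(bp$part1), length(bp$part2))
    smaller <- if (sizes[2L] < sizes[1L]) bp$part2 else bp$part1
    if (length(smaller) < 4L) {
      label <- "star"
      core <- smaller
    } else {
      label <- "bridge"
      core <- integer(0)
    }
  }
  structure(list(label = label, core = core, bipartition = bp),
            class = "archetype")
}

#' Nodal star, bridge, and cluster scores
#'
#' Summarizes how strongly each brain region participates in each hyperedge
#' archetype: the *star score* counts the star hyperedges in which the
#' region acts as a core; the *bridge score* sums the region's degree over
#' all bridge hyperedges (edges of bipartite hyperedges emanating from it);
#' the *cluster score* does the same over cluster hyperedges. When a
#' region-to-system map is supplied, each system's share of the total score
#' is normalized by the number of regions in the system.
#'
#' @param hyperedges List of `hyperedge` objects.
#' @param archetypes List of matching `archetype` labels (same order).
#' @param n_regions Total region count.
#' @param system_map Optional character/factor vector of length `n_regions`
#'   assigning every region to a named system.
#'
#' @return A list with `scores` — data frame (region, star_score,
#'   bridge_score, cluster_score) — and, when `system_map` is given,
#'   `system_percent`: a data frame of per-system percentages of each score
#'   normalized by system size.
#' @export
nodal_scores <- function(hyperedges, archetypes, n_regions, system_map = NULL) {
  if (length(hyperedges) != length(archetypes)) {
    stop("`hyperedges` and `archetypes` must align")
  }
  star <- bridge <- cluster <- numeric(n_regions)
  for (k in seq_along(hyperedges)) {
    h <- hyperedges[[k]]
    a <- archetypes[[k]]
    if (!is.null(h$pairs) && any(h$pairs > n_regions)) {
      stop("hyperedge ", h$id, " references a region outside 1..", n_regions)
    }
    if (a$label == "star") {
      star[a$core] <- star[a$core] + 1
    } else {
      deg <- tabulate(as.integer(h$pairs), nbins = n_regions)
      if (a$label == "bridge") bridge <- bridge + deg else cluster <- cluster + deg
    }
  }
  scores <- data.frame(region = seq_len(n_regions), star_score = star,
                       bridge_score = bridge, cluster_score = cluster)
  out <- list(scores = scores)
  if (!is.null(system_map)) {
    if (length(system_map) != n_regions) {
      stop("`system_map` must label every region")
    }
    sys <- factor(system_map)
    size <- as.integer(table(sys))
    pct <- function(x) {
      tot <- sum(x)
      by_sys <- tapply(x, sys, sum)
      if (tot == 0) rep(0, nlevels(sys)) else 100 * as.numeric(by_sys) / tot / size
    }
    out$system_percent <- data.frame(
      system = levels(sys), n_regions = size,
      star_pct = pct(star), bridge_pct = pct(bridge), cluster_pct = pct(cluster)
    )
  }
  out
}
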