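#' Fundamental modules from labelled hyperedges
#'
#' Collects the valid stars (cores of at most 3 regions) and the clusters as
#' the fundamental modules that bridges may connect. A star module's region
#' set is, by default, its full induced node set (core plus leaves); set
#' `star_regions = "core"` to use the cores alone.
#'
#' @param hyperedges List of `hyperedge` objects.
#' @param archetypes Matching list of `archetype` labels.
#' @param star_regions Either `"all"` (induced node set, default) or
#'   `"core"`.
#' @return A list of modules, each a list with `id`, `kind` (`"star"` or
#'   `"cluster"`), and `regions`.
#' @export
fundamental_modules <- function(hyperedges, archetypes, star_regions = c("all", "core")) {
  star_regions <- match.arg(star_regions)
  mods <- list()
  for (k in seq_along(hyperedges)) {
    a <- archetypes[[k]]
    if (a$label == "bridge") next
    regions <- if (a$label == "star") {
      if (length(a$core) < 1L || length(a$core) > 3L) next  # invalid star
      if (star_regions == "core") a$core else hyperedges[[k]]$nodes
    } else {
      hyperedges[[k]]$nodes
    }
    mods[[length(mods) + 1L]] <- list(id = hyperedges[[k]]$id,
                                      kind = a$label, regions = regions)
  }
  mods
}

#' Overlap of one bridge side with a fundamental module, with permutation P
#'
#' Counts the regions a bridge side shares with a module and compares the
#' count with a null in which the side is re-drawn uniformly from all
#' regions, preserving its size. The one-sided (upper tail) Monte-Carlo P
#' value uses the add-one correction \eqn{(1 + \#\{null \ge obs\})/(n_{null}+1)},
#' so it can never be exactly zero. With `method = "exact"` the null is
#' evaluated analytically: the overlap of a uniform size-preserving draw is
#' hypergeometric, so the tail probability replaces the Monte-Carlo
#' estimate (its n_null-to-infinity limit).
#'
#' @param side Region indices on one side of a bridge.
#' @param module_regions Region indices of the fundamental module.
#' @param n_regions Total number of regions to draw from.
#' @param n_null Number of null draws (default 10000).
#' @param seed Seed for the null draws.
#' @param method `"montecarlo"` (default) or `"exact"`.
#'
#' @return A list with `overlap` (observed count) and `p`.
#' @export
side_overlap_test <- function(side, module_regions, n_regions,
                              n_null = 10000L, seed = 1L,
                              method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  k <- length(side)
  if (k < 1L) stop("bridge side is empty")
  if (k > n_regions) stop("bridge side larger than the region set")
  obs <- length(intersect(side, module_regions))
  m <- length(module_regions)
  if (method == "exact") {
    p <- stats::phyper(obs - 1L, m, n_regions - m, k, lower.tail = FALSE)
  } else {
    set.seed(seed)
    null_overlap <- vapply(seq_len(n_null), function(r) {
      sum(sample.int(n_regions, k) %in% module_regions)
    }, 0L)
    p <- (1 + sum(null_overlap >= obs)) / (n_null + 1)
  }
  list(overlap = obs, p = p)
}

# observed overlaps and P values for every (bridge side, module) pair.
# Rows index sides (bridge 1 side 1, bridge 1 side 2, bridge 2 side 1, ...),
# columns index modules. Under the Monte-Carlo method one set of
# size-preserving draws per side is shared across all modules, mirroring
# the null ("each side randomly chosen, overlap computed with every
# fundamental module").
.overlap_pvals <- function(bridges, modules, n_regions, n_null, seed, method) {
  nb <- length(bridges)
  nm <- length(modules)
  sides <- vector("list", 2L * nb)
  for (b in seq_len(nb)) {
    sides[[2L * b - 1L]] <- bridges[[b]]$part1
    sides[[2L * b]] <- bridges[[b]]$part2
  }
  mod_ind <- matrix(FALSE, n_regions, nm)
  for (m in seq_len(nm)) mod_ind[modules[[m]]$regions, m] <- TRUE
  OV <- P <- matrix(0, 2L * nb, nm)
  if (method == "montecarlo") set.seed(seed)
  for (r in seq_along(sides)) {
    side <- sides[[r]]
    k <- length(side)
    if (k < 1L) stop("bridge side is empty")
    if (k > n_regions) stop("bridge side larger than the region set")
    OV[r, ] <- colSums(mod_ind[side, , drop = FALSE])
    if (method == "exact") {
      msz <- colSums(mod_ind)
      P[r, ] <- stats::phyper(OV[r, ] - 1, msz, n_regions - msz, k,
                              lower.tail = FALSE)
    } else {
      draws <- replicate(n_null, sample.int(n_regions, k))
      null_ov <- matrix(0L, n_null, nm)
      for (m in seq_len(nm)) {
        hits <- matrix(mod_ind[draws, m], nrow = k)
        null_ov[, m] <- colSums(hits)
      }
      P[r, ] <- (1 + colSums(null_ov >= rep(OV[r, ], each = n_null))) /
        (n_null + 1)
    }
  }
  list(overlap = OV, p = P)
}

# BH across all tests, then side kinds and bridge subtypes.
# A side matches the kind of its most significant module at q < Q.
.calls_from_p <- function(P, kinds, Q) {
  dims <- dim(P)
  q <- matrix(stats::p.adjust(P, method = "BH"), dims[1L], dims[2L])
  nb <- dims[1L] %/% 2L
  side_kind <- rep(NA_character_, dims[1L])
  for (r in seq_len(dims[1L])) {
    sig <- which(q[r, ] < Q)
    if (length(sig) == 0L) next
    best <- sig[order(q[r, sig], P[r, sig], kinds[sig])[1L]]
    side_kind[r] <- kinds[best]
  }
  side_kind <- matrix(side_kind, nb, 2L, byrow = TRUE)
  subtype <- vapply(seq_len(nb), function(b) {
    if (anyNA(side_kind[b, ])) return("unassigned")
    paste(sort(side_kind[b, ], decreasing = TRUE), collapse = "-")
  }, "")
  list(q = q, side_kind = side_kind, subtype = subtype)
}

#' Classify bridges by the fundamental modules their sides overlap
#'
#' For every bridge and each of its two sides, tests the overlap with every
#' fundamental module ([side_overlap_test()]); all (bridge, side, module) P
#' values are then jointly corrected by Benjamini-Hochberg. A side matches
#' the kind of its most significant module at `q < Q`; a bridge whose two
#' sides both match is classified as a `star-star`, `star-cluster`, or
#' `cluster-cluster` connector, and is `unassigned` otherwise.
#'
#' With many fundamental modules the joint BH family is large, and a
#' Monte-Carlo P value — floored at 1/(n_null+1) — cannot fall far enough
#' into the tail to survive the correction; `method = "exact"` (the same
#' null evaluated analytically) is then the appropriate choice and is what
#' [run_pipeline()] uses.
#'
#' @param bridges List of `bipartition` objects (one per bridge), or
#'   two-element lists with `part1`/`part2` region vectors.
#' @param modules Fundamental modules from [fundamental_modules()].
#' @param n_regions Total region count.
#' @param Q FDR level (default 0.05).
#' @param n_null,seed,method Passed to the overlap tests.
#'
#' @return A list of class `connector_result`: `calls` — data frame with
#'   one row per bridge (`bridge`, `subtype`, `side1_kind`, `side2_kind`) —
#'   and `tests` — the long (bridge, side, module, overlap, p, q) table.
#' @export
classify_connectors <- function(bridges, modules, n_regions, Q = 0.05,
                                n_null = 10000L, seed = 1L,
                                method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  if (length(bridges) < 1L) stop("no bridges supplied")
  if (length(modules) < 1L) stop("no fundamental modules supplied")
  kinds <- vapply(modules, `[[`, "", "kind")
  ov <- .overlap_pvals(bridges, modules, n_regions, n_null, seed, method)
  cc <- .calls_from_p(ov$p, kinds, Q)
  nb <- length(bridges)
  nm <- length(modules)
  calls <- data.frame(bridge = seq_len(nb),
                      subtype = cc$subtype,
                      side1_kind = cc$side_kind[, 1L],
                      side2_kind = cc$side_kind[, 2L])
  tests <- data.frame(
    bridge = rep(rep(seq_len(nb), each = 2L), times = nm),
    side   = rep(rep(1:2, times = nb), times = nm),
    module = rep(seq_len(nm), each = 2L * nb),
    overlap = as.vector(ov$overlap),
    p = as.vector(ov$p),
    q = as.vector(cc$q)
  )
  structure(list(calls = calls, tests = tests, Q = Q, n_regions = n_regions),
            class = "connector_result")
}

# per-replicate subtype counts under the size-preserving random-side null;
# inner overlap tests use the analytic hypergeometric tail
.subtype_null_counts <- function(bridges, modules, n_regions, Q, n_null, seed) {
  subtypes <- c("star-star", "star-cluster", "cluster-cluster")
  kinds <- vapply(modules, `[[`, "", "kind")
  k_side <- unlist(lapply(bridges, function(b) c(length(b$part1),
                                                 length(b$part2))))
  msz <- vapply(modules, function(m) length(m$regions), 0L)
  nr <- length(k_side)
  nm <- length(modules)
  Kmat <- matrix(rep(k_side, nm), nr, nm)
  Mmat <- matrix(rep(msz, each = nr), nr, nm)
  set.seed(seed)
  null_counts <- matrix(0L, n_null, length(subtypes),
                        dimnames = list(NULL, subtypes))
  for (r in seq_len(n_null)) {
    ovr <- matrix(stats::rhyper(nr * nm, as.vector(Mmat),
                                n_regions - as.vector(Mmat),
                                as.vector(Kmat)), nr, nm)
    P <- stats::phyper(ovr - 1, Mmat, n_regions - Mmat, Kmat,
                       lower.tail = FALSE)
    cc <- .calls_from_p(P, kinds, Q)
    null_counts[r, ] <- vapply(subtypes, function(s) sum(cc$subtype == s), 0L)
  }
  null_counts
}

#' Enrichment of connector subtypes against a size-preserving null
#'
#' Compares the observed number of assigned bridges of each subtype with a
#' null in which every bridge's two sides are re-drawn uniformly from all
#' regions (sizes preserved) and the full side-matching classification is
#' re-run. Counts are normalized by the number of possible bridges of each
#' subtype — the number of unordered module pairs with that kind
#' combination. The per-subtype P value is two-sided (doubled smaller tail,
#' add-one corrected, capped at 1). Inside the null replicates the side
#' overlap P values are evaluated analytically (hypergeometric tail), which
#' is the n_null-to-infinity limit of the Monte-Carlo test and keeps the
#' replicate loop tractable.
#'
#' @param result A `connector_result` holding the observed classification.
#' @param bridges The bridge list that produced `result` (side sizes are
#'   taken from it).
#' @param modules The fundamental modules used.
#' @param n_regions Total region count.
#' @param n_null Number of null replicates (default 10000).
#' @param seed Seed for the null draws.
#' @param keep_null If `TRUE`, return the per-replicate null count matrix.
#'
#' @return A list with `table` — data frame per subtype (`subtype`,
#'   `observed`, `possible`, `normalized` = observed/possible, `p`; subtypes
#'   with zero possible bridges get `NA`) — and, optionally, `null_counts`.
#' @export
subtype_enrichment <- function(result, bridges, modules, n_regions,
                               n_null = 10000L, seed = 1L, keep_null = FALSE) {
  stopifnot(inherits(result, "connector_result"))
  subtypes <- c("star-star", "star-cluster", "cluster-cluster")
  observed <- vapply(subtypes, function(s) sum(result$calls$subtype == s), 0L)
  if (sum(observed) < 1L) stop("no assigned bridges; enrichment undefined")
  kinds <- vapply(modules, `[[`, "", "kind")
  n_star <- sum(kinds == "star")
  n_clus <- sum(kinds == "cluster")
  possible <- c(
    "star-star"       = choose(n_star, 2),
    "star-cluster"    = n_star * n_clus,
    "cluster-cluster" = choose(n_clus, 2)
  )
  null_counts <- .subtype_null_counts(bridges, modules, n_regions,
                                      result$Q, n_null, seed)
  p <- vapply(seq_along(subtypes), function(k) {
    if (possible[k] == 0) return(NA_real_)
    up <- (1 + sum(null_counts[, k] >= observed[k])) / (n_null + 1)
    lo <- (1 + sum(null_counts[, k] <= observed[k])) / (n_null + 1)
    min(1, 2 * min(up, lo))
  }, 0)
  out <- list(table = data.frame(
    subtype = subtypes,
    observed = observed,
    possible = as.integer(possible),
    normalized = ifelse(possible > 0, observed / possible, NA_real_),
    p = p
  ))
  if (keep_null) out$null_counts <- null_counts
  out
}
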