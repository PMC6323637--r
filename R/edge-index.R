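#' Enumerate the network edges of an n-region parcellation
#'
#' Builds the canonical ordering of the \eqn{E = n(n-1)/2} unordered region
#' pairs used everywhere in the package: pairs \eqn{(i, j)} with \eqn{i < j}
#' in lexicographic order, so that a symmetric connectivity matrix can be
#' flattened to an edge vector and back without ambiguity. Region indices are
#' 1-based, matching R matrix indexing.
#'
#' @param n_regions Number of regions in the parcellation (at least 2).
#'
#' @return An object of class `edge_index`: a list with
#'   \describe{
#'     \item{n_regions}{the region count,}
#'     \item{pairs}{an E x 2 integer matrix of region pairs, row `m` holding
#'       the pair mapped to linear edge index `m`,}
#'     \item{n_edges}{E, the number of unordered pairs.}
#'   }
#'
#' @examples
#' idx <- build_edge_index(264)
#' idx$n_edges  # 34716
#'
#' @export
build_edge_index <- function(n_regions) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 2 ||
      n_regions != round(n_regions)) {
    stop("`n_regions` must be a single integer >= 2")
  }
  n_regions <- as.integer(n_regions)
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- sequence((n_regions - 1L):1L) + i
  structure(
    list(
      n_regions = n_regions,
      pairs     = cbind(i = i, j = j),
      n_edges   = length(i)
    ),
    class = "edge_index"
  )
}

#' Map a region pair to its linear edge index
#'
#' @param index An `edge_index` from [build_edge_index()].
#' @param i,j Region indices (1-based); order is irrelevant.
#' @return The linear index `m` of the unordered pair in `index$pairs`.
#' @export
pair_to_edge <- function(index, i, j) {
  stopifnot(inherits(index, "edge_index"))
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  n  <- index$n_regions
  if (any(lo < 1L | hi > n | lo == hi)) {
    stop("region pair out of range or degenerate")
  }
  # edges preceding row block lo, plus offset within the block
  as.integer((lo - 1L) * n - lo * (lo - 1L) / 2 + (hi - lo))
}

#' Map linear edge indices back to region pairs
#'
#' @param index An `edge_index`.
#' @param m Linear edge indices.
#' @return An integer matrix with columns `i`, `j`.
#' @export
edge_to_pair <- function(index, m) {
  stopifnot(inherits(index, "edge_index"))
  if (any(m < 1L | m > index$n_edges)) stop("edge index out of range")
  index$pairs[m, , drop = FALSE]
}

#' @export
print.edge_index <- function(x, ...) {
  cat("<edge_index> ", x$n_regions, " regions, ", x$n_edges, " edges\n", sep = "")
  invisible(x)
}
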