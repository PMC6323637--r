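#' Stack per-subject connectomes into an adjacency tensor
#'
#' Concatenates a cohort's symmetric region-by-region connectivity matrices
#' into a three-dimensional array with elements `A[i, j, s]`, where `s`
#' indexes subjects in the order supplied.
#'
#' @param connectomes A list of symmetric numeric matrices of identical
#'   dimension, one per subject, with zero diagonal.
#' @param subject_ids Optional character vector of subject identifiers;
#'   defaults to the list names or `sub001`-style labels.
#' @param tol Symmetry tolerance.
#'
#' @return A numeric array of dimension `n_regions x n_regions x n_subjects`
#'   with class `adjacency_tensor` and a `subject_ids` attribute.
#'
#' @export
stack_connectomes <- function(connectomes, subject_ids = NULL, tol = 1e-8) {
  if (!is.list(connectomes) || length(connectomes) < 1L) {
    stop("`connectomes` must be a nonempty list of matrices")
  }
  n <- nrow(connectomes[[1L]])
  S <- length(connectomes)
  if (is.null(subject_ids)) {
    subject_ids <- names(connectomes)
    if (is.null(subject_ids)) {
      subject_ids <- sprintf("sub%03d", seq_len(S))
    }
  }
  for (s in seq_len(S)) {
    A <- connectomes[[s]]
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n) {
      stop("connectome for subject '", subject_ids[s], "' is not a ", n, "x", n, " matrix")
    }
    if (max(abs(A - t(A))) > tol) {
      stop("connectome for subject '", subject_ids[s], "' is not symmetric")
    }
  }
  tensor <- array(unlist(connectomes, use.names = FALSE), dim = c(n, n, S))
  structure(tensor, class = "adjacency_tensor", subject_ids = subject_ids)
}

#' Extract per-edge weight vectors from an adjacency tensor
#'
#' Flattens the upper triangle of every subject's connectivity matrix into
#' rows of an edge-by-subject weight matrix: row `m` holds the weight of
#' edge `m` (per the [build_edge_index()] ordering) across the cohort. Edges
#' whose across-subject mean weight does not exceed `min_strength` are
#' dropped — weak connections carry little covariance signal and their
#' near-constant rows destabilise the edge-pair correlations downstream.
#'
#' @param tensor An `adjacency_tensor` (regions x regions x subjects).
#' @param index The matching `edge_index`; built from the tensor dimension
#'   when omitted.
#' @param min_strength Retention threshold on the across-subject mean edge
#'   weight (default 0.07); an edge is kept only if its mean weight is
#'   strictly greater.
#'
#' @return A numeric matrix (retained edges x subjects) of class
#'   `edge_weight_matrix` with attributes `edge_index` (the full index),
#'   `edges` (linear indices of retained edges), `pairs` (their region
#'   pairs), and `min_strength`.
#'
#' @export
extract_edge_vectors <- function(tensor, index = NULL, min_strength = 0.07) {
  d <- dim(tensor)
  if (length(d) != 3L || d[1L] != d[2L]) {
    stop("`tensor` must be a regions x regions x subjects array")
  }
  n <- d[1L]
  S <- d[3L]
  if (is.null(index)) index <- build_edge_index(n)
  if (index$n_regions != n) stop("`index` does not match the tensor dimension")
  ut <- upper.tri(matrix(0, n, n))
  # column-major upper triangle is ordered by (j, i); reorder to the
  # lexicographic (i, j) ordering of the edge index
  ut_i <- row(ut)[ut]
  ut_j <- col(ut)[ut]
  ord  <- order(ut_i, ut_j)
  W <- matrix(0, nrow = index$n_edges, ncol = S)
  for (s in seq_len(S)) {
    slice <- tensor[, , s]
    W[, s] <- slice[ut][ord]
  }
  keep <- rowMeans(W) > min_strength
  structure(
    W[keep, , drop = FALSE],
    class        = "edge_weight_matrix",
    edge_index   = index,
    edges        = which(keep),
    pairs        = index$pairs[keep, , drop = FALSE],
    min_strength = min_strength,
    subject_ids  = attr(tensor, "subject_ids")
  )
}

#' Build the thresholded edge-by-edge hypergraph
#'
#' Correlates every pair of edge weight vectors across subjects (Pearson),
#' yielding the E x E matrix `H` whose entry `H[m, n]` measures how strongly
#' edges `m` and `n` co-vary over the cohort. To control false positives,
#' entries whose two-sided P value (t distribution, `S - 2` df) exceeds
#' `alpha` are set to zero; surviving negative correlations are then also
#' zeroed, after recording their prevalence, so that the community detection
#' stage operates on a nonnegative similarity matrix.
#'
#' @param W An `edge_weight_matrix` from [extract_edge_vectors()] (or any
#'   numeric matrix of edges x subjects with at least 3 columns).
#' @param alpha Significance level for the per-entry correlation test
#'   (default 0.05, uncorrected).
#' @param block_size Number of rows correlated per block; blocks bound peak
#'   memory when E is large and do not change the result.
#'
#' @return A symmetric nonnegative E x E matrix of class `hypergraph` with
#'   zero diagonal and attributes `alpha`, `fraction_negative` (proportion
#'   of significance-surviving off-diagonal entries that were negative
#'   before zeroing), `edges` and `pairs` (copied from `W` when present).
#'
#' @export
build_hypergraph <- function(W, alpha = 0.05, block_size = 4096L) {
  W <- unclass(W)
  E <- nrow(W)
  S <- ncol(W)
  if (S < 3L) stop("at least 3 subjects are required to correlate edge weights")
  sds <- apply(W, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1L]
    stop("edge row ", bad, " is constant across subjects; correlation undefined")
  }
  # standardized rows: correlation = Z %*% t(Z) / (S - 1)
  Z <- (W - rowMeans(W)) / sds
  H <- matrix(0, E, E)
  tcrit <- function(r) {
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((S - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = S - 2)
  }
  n_neg <- 0L
  n_sig <- 0L
  starts <- seq.int(1L, E, by = block_size)
  for (b in starts) {
    rows <- b:min(b + block_size - 1L, E)
    Rblk <- tcrossprod(Z[rows, , drop = FALSE], Z) / (S - 1)
    P    <- tcrit(Rblk)
    Rblk[P > alpha] <- 0
    # diagonal block: zero self-correlations
    Rblk[cbind(seq_along(rows), rows)] <- 0
    n_sig <- n_sig + sum(Rblk != 0)
    n_neg <- n_neg + sum(Rblk < 0)
    Rblk[Rblk < 0] <- 0
    H[rows, ] <- Rblk
  }
  H <- (H + t(H)) / 2  # guard against one-ulp asymmetry from blockwise BLAS
  structure(
    H,
    class             = "hypergraph",
    alpha             = alpha,
    fraction_negative = if (n_sig > 0) n_neg / n_sig else 0,
    edges             = attr(W, "edges"),
    pairs             = attr(W, "pairs")
  )
}
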