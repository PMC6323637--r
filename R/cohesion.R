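#' Pairwise cross-subject correlations among a module's edges
#'
#' For a predefined module (a set of regions, e.g. a cognitive system),
#' collects every retained edge whose both endpoints lie in the module and
#' returns all pairwise Pearson correlations of their weight vectors across
#' subjects — the module's distribution of edge cohesion.
#'
#' @param W An `edge_weight_matrix` from [extract_edge_vectors()].
#' @param module_regions Region indices of the module.
#' @param module_name Name used in error messages.
#' @return Numeric vector of the \eqn{\binom{k}{2}} pairwise correlations
#'   among the `k` within-module edges.
#' @export
module_edge_cohesion <- function(W, module_regions, module_name = "module") {
  pairs <- attr(W, "pairs")
  if (is.null(pairs)) stop("`W` carries no edge pair information")
  inside <- pairs[, 1L] %in% module_regions & pairs[, 2L] %in% module_regions
  k <- sum(inside)
  if (k < 2L) {
    stop("module '", module_name, "' has ", k,
         " retained within-module edge(s); at least 2 are needed")
  }
  R <- stats::cor(t(unclass(W)[inside, , drop = FALSE]))
  R[upper.tri(R)]
}

#' Mean pairwise correlation of each star's member edges
#'
#' For every star hyperedge whose core lies in the module, computes the mean
#' of the pairwise cross-subject correlations among its member edges. Stars
#' with a single member edge have no pairs and are excluded (reported in the
#' `excluded` attribute).
#'
#' @param W An `edge_weight_matrix`.
#' @param stars List of `hyperedge` objects (star-labelled).
#' @return Numeric vector of per-star mean pairwise correlations, with an
#'   `excluded` attribute listing single-edge stars.
#' @export
star_cohesion <- function(W, stars) {
  means <- numeric(0)
  excluded <- integer(0)
  for (h in stars) {
    if (h$size < 2L) {
      excluded <- c(excluded, h$id)
      next
    }
    R <- stats::cor(t(unclass(W)[h$members, , drop = FALSE]))
    means <- c(means, mean(R[upper.tri(R)]))
  }
  attr(means, "excluded") <- excluded
  means
}

# Storey-type q values with a fixed lambda; used as an alternative to BH
.storey_q <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    prev <- min(prev, pi0 * m * p[i] / (m - k + 1))
    q[i] <- prev
  }
  q
}

#' Compare star cohesion against predefined modules
#'
#' Tests, for each module, the null hypothesis that the pairwise similarity
#' of edges in stars centered within the module is no higher than that of
#' the edges within the module overall. The default test is a one-sided
#' Mann-Whitney rank-sum (stars greater); a permutation test on the mean
#' difference is available as an alternative. P values are corrected across
#' modules (BH by default, or a Storey-type q value).
#'
#' @param module_dists Named list: per module, the correlation distribution
#'   from [module_edge_cohesion()] (or `NULL` if the module was untestable).
#' @param star_means Named list: per module, the star means from
#'   [star_cohesion()].
#' @param test `"ranksum"` (default) or `"permutation"`.
#' @param fdr `"BH"` (default) or `"storey"`.
#' @param n_perm Permutations for the permutation variant.
#' @param seed Seed for the permutation variant.
#' @param small_module_n Modules with fewer within-module edge pairs than
#'   this are flagged `low_power` in the output (default 10).
#'
#' @return Data frame with one row per module: `module`, `n_edge_pairs`,
#'   `n_stars`, `statistic`, `p`, `q`, `low_power`, `testable`.
#' @export
compare_cohesion <- function(module_dists, star_means,
                             test = c("ranksum", "permutation"),
                             fdr = c("BH", "storey"),
                             n_perm = 10000L, seed = 1L,
                             small_module_n = 10L) {
  test <- match.arg(test)
  fdr <- match.arg(fdr)
  mods <- names(module_dists)
  if (is.null(mods)) mods <- as.character(seq_along(module_dists))
  rows <- lapply(mods, function(m) {
    x <- star_means[[m]]
    y <- module_dists[[m]]
    testable <- !is.null(y) && length(y) >= 1L && !is.null(x) && length(x) >= 1L
    if (!testable) {
      return(data.frame(module = m, n_edge_pairs = length(y),
                        n_stars = length(x), statistic = NA_real_,
                        p = NA_real_, low_power = TRUE, testable = FALSE))
    }
    if (test == "ranksum") {
      wt <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                               correct = TRUE)
      stat <- unname(wt$statistic)
      p <- wt$p.value
    } else {
      set.seed(seed)
      obs <- mean(x) - mean(y)
      pool <- c(x, y)
      nx <- length(x)
      null <- vapply(seq_len(n_perm), function(r) {
        idx <- sample.int(length(pool), nx)
        mean(pool[idx]) - mean(pool[-idx])
      }, 0)
      stat <- obs
      p <- (1 + sum(null >= obs)) / (n_perm + 1)
    }
    data.frame(module = m, n_edge_pairs = length(y), n_stars = length(x),
               statistic = stat, p = p,
               low_power = length(y) < small_module_n, testable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- out$testable
  if (any(ok)) {
    out$q[ok] <- if (fdr == "BH") {
      stats::p.adjust(out$p[ok], method = "BH")
    } else {
      .storey_q(out$p[ok])
    }
  }
  out[, c("module", "n_edge_pairs", "n_stars", "statistic", "p", "q",
          "low_power", "testable")]
}
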