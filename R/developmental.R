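#' Per-subject mean strength of a hyperedge
#'
#' Maps a hyperedge back onto each subject's connectivity matrix and
#' averages its member edges' weights, yielding one strength value per
#' subject.
#'
#' @param tensor An `adjacency_tensor`.
#' @param h A `hyperedge` (its `pairs` are used), or a two-column matrix of
#'   region pairs.
#' @return Numeric vector of length `n_subjects`.
#' @export
hyperedge_strength <- function(tensor, h) {
  pairs <- if (inherits(h, "hyperedge")) h$pairs else h
  if (is.null(pairs) || nrow(pairs) < 1L) stop("hyperedge has no member edges")
  d <- dim(tensor)
  if (max(pairs) > d[1L]) stop("hyperedge references regions outside the tensor")
  S <- d[3L]
  vapply(seq_len(S), function(s) {
    mean(tensor[, , s][pairs])
  }, 0)
}

#' Linear model of hyperedge strength on age, adjusting for motion
#'
#' Fits ordinary least squares `strength ~ age + motion` and reports the
#' overall model F against the intercept-only fit (numerator df 2), the t
#' and two-sided P value of the age coefficient, and the partial correlation
#' between strength and age controlling for motion (the correlation of the
#' two motion-residualized variables) with its t-based P value.
#'
#' @param strength Per-subject strength vector.
#' @param covariates Data frame with columns `age` and `motion`, rows
#'   aligned with `strength`.
#' @param age_only_f If `TRUE`, the F statistic tests the age term alone
#'   (numerator df 1) instead of age and motion jointly.
#' @param cond_limit Condition-number limit on the scaled design matrix
#'   above which the fit aborts as collinear.
#'
#' @return A list of class `age_effect` with `coefficients`, `F`, `df`,
#'   `model_p`, `age_t`, `age_p`, `partial_r`, `partial_p`, `n`.
#' @export
age_model <- function(strength, covariates, age_only_f = FALSE,
                      cond_limit = 1e8) {
  age <- covariates$age
  motion <- covariates$motion
  n <- length(strength)
  if (n < 4L) stop("at least 4 subjects are required")
  if (length(age) != n || length(motion) != n) {
    stop("covariates are not aligned with `strength`")
  }
  X <- cbind(1, scale(age), scale(motion))
  kappa_x <- kappa(X, exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > cond_limit) {
    stop("age and motion are collinear (condition number ", format(kappa_x), ")")
  }
  fit <- stats::lm(strength ~ age + motion)
  sm <- summary(fit)
  if (age_only_f) {
    f <- sm$coefficients["age", "t value"]^2
    df <- c(1, fit$df.residual)
  } else {
    f <- unname(sm$fstatistic[1L])
    df <- unname(sm$fstatistic[2:3])
  }
  model_p <- stats::pf(f, df[1L], df[2L], lower.tail = FALSE)
  r_s <- stats::resid(stats::lm(strength ~ motion))
  r_a <- stats::resid(stats::lm(age ~ motion))
  pr <- stats::cor(r_s, r_a)
  t_pr <- pr * sqrt((n - 3) / max(1 - pr^2, .Machine$double.eps))
  partial_p <- 2 * stats::pt(-abs(t_pr), df = n - 3)
  structure(
    list(coefficients = stats::coef(fit), F = f, df = df, model_p = model_p,
         age_t = sm$coefficients["age", "t value"],
         age_p = sm$coefficients["age", "Pr(>|t|)"],
         partial_r = pr, partial_p = partial_p, n = n),
    class = "age_effect"
  )
}

#' Compare age associations across hyperedge archetype classes
#'
#' Groups the per-hyperedge partial correlations (strength vs age given
#' motion) by archetype class and tests whether classes differ: a one-way
#' ANOVA across classes with at least `min_class` members, pairwise
#' post-hoc permutation tests on the class mean difference (one-sided,
#' first class greater, by default), and a BH-FDR mask over all hyperedges'
#' partial-correlation P values at level `fdr_q`.
#'
#' @param age_effects List of `age_effect` objects, one per hyperedge.
#' @param labels Character vector of archetype labels, same order.
#' @param n_perm Permutations per post-hoc pair (default 10000).
#' @param seed Seed for the permutations.
#' @param fdr_q FDR level for the per-hyperedge mask (default 0.01).
#' @param two_sided If `TRUE`, post-hoc P values are two-sided.
#' @param min_class Minimum class size entering the ANOVA (default 2).
#'
#' @return A list with `anova` (`F`, `df`, `p`), `posthoc` (data frame of
#'   pairwise class comparisons, ordered so the class with the larger mean
#'   comes first), `partial_r` / `partial_p` per hyperedge, `fdr_mask`
#'   (logical, q <= `fdr_q`), `q`, and `excluded_classes`.
#' @export
class_comparison <- function(age_effects, labels, n_perm = 10000L, seed = 1L,
                             fdr_q = 0.01, two_sided = FALSE, min_class = 2L) {
  r <- vapply(age_effects, `[[`, 0, "partial_r")
  p <- vapply(age_effects, `[[`, 0, "partial_p")
  labels <- as.character(labels)
  if (length(labels) != length(r)) stop("`labels` must align with `age_effects`")
  counts <- table(labels)
  keep_classes <- names(counts)[counts >= min_class]
  excluded <- setdiff(names(counts), keep_classes)
  if (length(keep_classes) < 2L) {
    stop("need at least 2 classes with >= ", min_class, " hyperedges")
  }
  in_aov <- labels %in% keep_classes
  grp <- factor(labels[in_aov], levels = keep_classes)
  fit <- stats::aov(r[in_aov] ~ grp)
  av <- summary(fit)[[1L]]
  anova_res <- list(F = av[["F value"]][1L],
                    df = c(av[["Df"]][1L], av[["Df"]][2L]),
                    p = av[["Pr(>F)"]][1L])
  set.seed(seed)
  combs <- utils::combn(keep_classes, 2L)
  posthoc <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1L, k]; b <- combs[2L, k]
    xa <- r[labels == a]; xb <- r[labels == b]
    # orient so the class with the larger observed mean is tested as greater
    if (mean(xb) > mean(xa)) { tmp <- a; a <- b; b <- tmp; tmp <- xa; xa <- xb; xb <- tmp }
    obs <- mean(xa) - mean(xb)
    pool <- c(xa, xb)
    na <- length(xa)
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      mean(pool[idx]) - mean(pool[-idx])
    }, 0)
    pp <- if (two_sided) {
      (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    } else {
      (1 + sum(null >= obs)) / (n_perm + 1)
    }
    data.frame(greater = a, lesser = b, mean_diff = obs, p = pp)
  })
  q <- stats::p.adjust(p, method = "BH")
  list(anova = anova_res, posthoc = do.call(rbind, posthoc),
       partial_r = r, partial_p = p, q = q, fdr_mask = q <= fdr_q,
       excluded_classes = excluded)
}
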