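# Independent brute-force oracles used across the test files. These
# deliberately avoid the package's computational paths: direct summation,
# exhaustive enumeration, and closed forms only.

# --- wavelet coherence: time-domain CWT + direct-sum smoothing -------------

oracle_cwt <- function(x, dt, scales) {
  N <- length(x)
  x <- x - mean(x)
  W <- matrix(0 + 0i, length(scales), N)
  omega0 <- 6
  for (u in seq_along(scales)) {
    s <- scales[u]
    for (t in seq_len(N)) {
      eta <- ((seq_len(N) - t) * dt) / s
      psi <- pi^(-1 / 4) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
      W[u, t] <- sum(x * Conj(psi)) * sqrt(dt / s)
    }
  }
  W
}

oracle_smooth <- function(field, dt, scales, hw = 3L) {
  ns <- nrow(field)
  N <- ncol(field)
  tim <- field
  for (u in seq_len(ns)) {
    s <- scales[u]
    for (t in seq_len(N)) {
      g <- exp(-(((seq_len(N)) - t) * dt)^2 / (2 * s^2))
      h <- min(N - 1L, ceiling(4 * s / dt))
      g[abs(seq_len(N) - t) > h] <- 0
      gh <- exp(-((((-h):h)) * dt)^2 / (2 * s^2))
      tim[u, t] <- sum(field[u, ] * g) / sum(gh)
    }
  }
  out <- tim
  for (u in seq_len(ns)) {
    win <- max(1L, u - hw):min(ns, u + hw)
    out[u, ] <- colMeans(tim[win, , drop = FALSE])
  }
  out
}

oracle_wavelet_coherence <- function(x, y, dt, band) {
  prep <- edgehyper:::.coherence_prep(length(x), dt, band)
  Wx <- oracle_cwt(x, dt, prep$scales)
  Wy <- oracle_cwt(y, dt, prep$scales)
  Sx <- Re(oracle_smooth(abs(Wx)^2 / prep$scales, dt, prep$scales))
  Sy <- Re(oracle_smooth(abs(Wy)^2 / prep$scales, dt, prep$scales))
  Sxy <- oracle_smooth(Wx * Conj(Wy) / prep$scales, dt, prep$scales)
  R2 <- pmin(pmax(abs(Sxy)^2 / (Sx * Sy), 0), 1)
  mean(R2[prep$use])
}

# --- hypergraph: per-entry Pearson + t test --------------------------------

oracle_hypergraph <- function(W, alpha = 0.05) {
  E <- nrow(W)
  S <- ncol(W)
  H <- matrix(0, E, E)
  for (m in seq_len(E - 1L)) {
    for (n in (m + 1L):E) {
      ct <- stats::cor.test(W[m, ], W[n, ], method = "pearson")
      r <- unname(ct$estimate)
      if (ct$p.value <= alpha && r > 0) {
        H[m, n] <- H[n, m] <- r
      }
    }
  }
  H
}

# --- modularity: literal double sum ----------------------------------------

oracle_modularity <- function(H, labels, gamma = 1) {
  E <- nrow(H)
  k <- colSums(H)
  w2 <- sum(k)
  q <- 0
  for (m in seq_len(E)) {
    for (n in seq_len(E)) {
      if (labels[m] == labels[n]) {
        q <- q + H[m, n] - gamma * k[m] * k[n] / w2
      }
    }
  }
  q / w2
}

# --- max cut: enumeration over subsets via combn ---------------------------

oracle_maxcut <- function(B) {
  n <- nrow(B)
  best <- 0
  for (k in 1:(n - 1L)) {
    subs <- utils::combn(n, k)
    for (c in seq_len(ncol(subs))) {
      part <- subs[, c]
      cut <- sum(B[part, setdiff(seq_len(n), part), drop = FALSE])
      if (cut > best) best <- cut
    }
  }
  best
}

# --- one-sided rank-sum p by exhaustive enumeration (small samples) --------

oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  ranks <- rank(pool)
  obs <- sum(ranks[seq_len(nx)])
  subs <- utils::combn(length(pool), nx)
  stats_all <- apply(subs, 2L, function(idx) sum(ranks[idx]))
  mean(stats_all >= obs)
}

# --- OLS by normal equations + partial correlation from residuals ----------

oracle_ols_age <- function(strength, age, motion) {
  X <- cbind(1, age, motion)
  beta <- solve(t(X) %*% X, t(X) %*% strength)
  resid <- strength - X %*% beta
  n <- length(strength)
  df <- n - 3L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(t(X) %*% X)) * sigma2)
  t_age <- beta[2L] / se[2L]
  # partial correlation via explicit residualization
  Xm <- cbind(1, motion)
  rs <- strength - Xm %*% solve(t(Xm) %*% Xm, t(Xm) %*% strength)
  ra <- age - Xm %*% solve(t(Xm) %*% Xm, t(Xm) %*% age)
  list(beta = as.numeric(beta), t_age = t_age,
       partial_r = sum(rs * ra) / sqrt(sum(rs^2) * sum(ra^2)))
}

# --- one-way ANOVA F from explicit sums of squares -------------------------

oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  (ss_between / df1) / (ss_within / df2)
}

# --- adjusted Rand index (mclust) ------------------------------------------

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# --- small toy graphs ------------------------------------------------------

complete_bipartite_pairs <- function(m, n) {
  edgehyper:::.cross_pairs(seq_len(m), m + seq_len(n))
}

clique_pairs <- function(n) {
  pr <- t(utils::combn(seq_len(n), 2L))
  colnames(pr) <- c("i", "j")
  pr
}

cycle_pairs <- function(n) {
  cbind(i = pmin(seq_len(n), c(2:n, 1L)), j = pmax(seq_len(n), c(2:n, 1L)))
}
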