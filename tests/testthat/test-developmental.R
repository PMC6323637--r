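test_that("hyperedge strength is the member-edge mean per subject", {
  set.seed(21)
  coh <- generate_cohort(synthetic_spec(8, 10, groups = list(), seed = 21))
  pairs <- cbind(i = c(1, 2, 3), j = c(2, 4, 5))
  s <- hyperedge_strength(coh$tensor, pairs)
  # direct scan oracle
  expected <- vapply(1:10, function(k) {
    mean(c(coh$tensor[1, 2, k], coh$tensor[2, 4, k], coh$tensor[3, 5, k]))
  }, 0)
  expect_equal(s, expected, tolerance = 1e-12)
  # single-edge hyperedge returns that edge's weights
  s1 <- hyperedge_strength(coh$tensor, cbind(i = 1, j = 2))
  expect_equal(s1, coh$tensor[1, 2, ], tolerance = 1e-15)
  # constant tensor gives constant strength
  ten <- array(0.5, dim = c(4, 4, 3))
  for (k in 1:3) diag(ten[, , k]) <- 0
  expect_equal(hyperedge_strength(ten, cbind(i = c(1, 2), j = c(2, 3))),
               rep(0.5, 3))
  expect_error(hyperedge_strength(coh$tensor, cbind(i = 1, j = 99)),
               "outside the tensor")
})

test_that("age model matches the normal-equations oracle", {
  set.seed(22)
  n <- 20
  covars <- data.frame(age = runif(n, 8, 22), motion = rlnorm(n, -1, 0.5))
  strength <- 0.3 + 0.01 * covars$age - 0.02 * covars$motion + rnorm(n, sd = 0.02)
  eff <- age_model(strength, covars)
  orc <- oracle_ols_age(strength, covars$age, covars$motion)
  expect_equal(unname(eff$coefficients), orc$beta, tolerance = 1e-10)
  expect_equal(unname(eff$age_t), unname(orc$t_age), tolerance = 1e-10)
  expect_equal(eff$partial_r, orc$partial_r, tolerance = 1e-10)
  expect_equal(eff$df, c(2, n - 3))
})

test_that("exact linear dependence on age gives partial r of one", {
  set.seed(23)
  n <- 30
  covars <- data.frame(age = runif(n, 8, 22), motion = rlnorm(n, -1, 0.5))
  strength <- 0.01 * covars$age
  eff <- age_model(strength, covars)
  expect_equal(eff$partial_r, 1, tolerance = 1e-8)
  expect_lt(eff$age_p, 1e-20)
  # affine rescaling of the inputs leaves the partial correlation unchanged
  eff2 <- age_model(strength * 50 - 1,
                    transform(covars, age = age / 10, motion = motion * 3))
  expect_equal(eff2$partial_r, eff$partial_r, tolerance = 1e-8)
  # collinearity is refused
  expect_error(age_model(strength,
                         data.frame(age = covars$age, motion = 2 * covars$age)),
               "collinear")
})

test_that("age-coefficient p is uniform when there is no age effect", {
  set.seed(24)
  n <- 40
  ps <- vapply(1:1000, function(r) {
    covars <- data.frame(age = runif(n, 8, 22), motion = rlnorm(n, -1, 0.5))
    age_model(rnorm(n), covars)$age_p
  }, 0)
  ks <- ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

fake_effects <- function(r_values) {
  lapply(r_values, function(r) {
    structure(list(partial_r = r,
                   partial_p = 2 * pt(-abs(r * sqrt(50)), df = 50)),
              class = "age_effect")
  })
}

test_that("class comparison recovers a planted cluster-specific age effect", {
  hits <- vapply(1:50, function(seed) {
    groups <- c(
      lapply(1:4, function(k) {
        star_group(core = (k - 1) * 7 + 1, leaves = (k - 1) * 7 + 2:7,
                   beta = 0.2, gamma = 0)
      }),
      lapply(1:4, function(k) {
        cluster_group(members = 28 + (k - 1) * 6 + 1:6, beta = 0.2,
                      gamma = 0.1)
      })
    )
    spec <- synthetic_spec(60, 200, groups = groups, seed = 3000 + seed)
    coh <- generate_cohort(spec)
    effects <- lapply(coh$truth$groups, function(g) {
      age_model(hyperedge_strength(coh$tensor, g$pairs), coh$covariates)
    })
    labels <- vapply(coh$truth$groups, `[[`, "", "topology")
    res <- class_comparison(effects, labels, n_perm = 500, seed = seed)
    ph <- res$posthoc
    row <- ph[ph$greater == "cluster" & ph$lesser == "star", ]
    nrow(row) == 1 && row$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("ANOVA agrees with a sums-of-squares oracle and is calibrated", {
  set.seed(25)
  r <- rnorm(12, sd = 0.1)
  labels <- rep(c("star", "bridge", "cluster"), each = 4)
  res <- class_comparison(fake_effects(r), labels, n_perm = 200, seed = 1)
  expect_equal(res$anova$F, oracle_anova_f(r, labels), tolerance = 1e-10)
  expect_equal(res$anova$df[1], 2)
  # identical groups: permutation p near 0.5
  r2 <- rep(c(0.1, 0.2, 0.15, 0.12), 2)
  res2 <- class_comparison(fake_effects(r2), rep(c("a", "b"), each = 4),
                           n_perm = 2000, seed = 2)
  expect_gt(res2$posthoc$p, 0.3)
  # p uniform when all classes share a distribution
  ps <- vapply(1:500, function(k) {
    rr <- rnorm(15, sd = 0.1)
    class_comparison(fake_effects(rr), rep(c("a", "b", "c"), each = 5),
                     n_perm = 2, seed = k)$anova$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("FDR mask stays at or below q under the global null", {
  set.seed(26)
  rates <- vapply(1:50, function(k) {
    n <- 40
    covars <- data.frame(age = runif(n, 8, 22), motion = rlnorm(n, -1, 0.5))
    effects <- lapply(1:12, function(j) age_model(rnorm(n), covars))
    res <- class_comparison(effects, rep(c("star", "cluster"), 6),
                            n_perm = 2, seed = k, fdr_q = 0.01)
    mean(res$fdr_mask)
  }, 0)
  expect_lte(mean(rates), 0.01 + 0.005)
})

test_that("small classes are excluded with a record", {
  r <- rnorm(7, sd = 0.1)
  labels <- c(rep("star", 4), rep("cluster", 2), "bridge")
  res <- class_comparison(fake_effects(r), labels, n_perm = 100, seed = 3)
  expect_equal(res$excluded_classes, "bridge")
  expect_error(class_comparison(fake_effects(r[1:3]), c("a", "a", "b"),
                                n_perm = 10, seed = 1),
               "at least 2 classes")
})
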