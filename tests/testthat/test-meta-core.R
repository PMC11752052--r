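test_that("pooling handles the degenerate and homogeneous cases", {
  r <- pool_random_effects(0.4, 0.01)
  expect_equal(r$k, 1L)
  expect_equal(r$pooled, 0.4)
  expect_equal(r$tau2, 0)
  expect_equal(r$se, 0.1)
  r <- pool_random_effects(rep(0.25, 3), c(0.01, 0.02, 0.04))
  expect_equal(r$pooled, 0.25)
  expect_equal(r$q, 0)
  expect_equal(r$tau2, 0)
  expect_error(pool_random_effects(numeric(0), numeric(0)), "no estimates")
  expect_error(pool_random_effects(c(0.1, 0.2), c(0.01, 0)), "variance > 0")
})

test_that("DerSimonian-Laird matches the hand-computed toy example", {
  r <- pool_random_effects(c(0.1, 0.3, 0.5), rep(0.01, 3), method = "DL")
  expect_equal(r$q, 8, tolerance = 1e-12)
  expect_equal(r$tau2, 0.03, tolerance = 1e-12)  # (8 - 2) / (300 - 100)
  expect_equal(r$pooled, 0.3, tolerance = 1e-12)
})

test_that("REML tau2 matches a brute-force grid search and the independent library", {
  set.seed(4)
  y <- c(-0.42, 0.11, 0.78, 0.35, -0.15)
  v <- c(0.021, 0.05, 0.013, 0.08, 0.034)
  mine <- pool_random_effects(y, v, method = "REML")
  grid <- oracle_reml_tau2(y, v, upper = 1, step = 1e-5)
  expect_equal(mine$tau2, grid, tolerance = 2e-5)
  skip_if_not_installed("metafor")
  mf <- metafor::rma(y, v, method = "REML")
  expect_equal(mine$tau2, mf$tau2, tolerance = 1e-4)
  expect_equal(mine$pooled, as.numeric(mf$beta), tolerance = 1e-6)
  expect_equal(mine$se, mf$se, tolerance = 1e-4)
})

test_that("DL and REML agree when the truncation binds", {
  y <- c(0.30, 0.31, 0.29, 0.30)
  v <- rep(0.05, 4)   # Q well below k - 1
  dl <- pool_random_effects(y, v, method = "DL")
  reml <- pool_random_effects(y, v, method = "REML")
  expect_lt(dl$q, 3)
  expect_equal(dl$tau2, 0)
  expect_equal(reml$tau2, 0)
  expect_equal(dl$pooled, reml$pooled)
  # with tau2 = 0 the pooled value is the closed-form fixed-effect mean
  expect_equal(dl$pooled, sum(y / v) / sum(1 / v), tolerance = 1e-12)
})

test_that("subgroup Q test matches hand computation and its limits", {
  two <- list(a = pool_random_effects(0.37, 0.02^2),
              b = pool_random_effects(0.42, 0.01^2))
  sg <- subgroup_difference(two)
  expect_equal(sg$q_between, 5, tolerance = 1e-10)
  expect_equal(sg$df, 1L)
  expect_equal(sg$p, pchisq(5, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(sg$p, 4), 0.0253)
  # identical subgroups: Q = 0, p = 1
  same <- list(a = pool_random_effects(0.4, 0.01), b = pool_random_effects(0.4, 0.01))
  sg0 <- subgroup_difference(same)
  expect_equal(sg0$q_between, 0)
  expect_equal(sg0$p, 1)
  # a third subgroup with enormous SE contributes ~zero weight
  three <- c(two, list(c = pool_random_effects(0.1, 1e8)))
  expect_equal(subgroup_difference(three)$q_between, sg$q_between,
               tolerance = 1e-4)
  expect_error(subgroup_difference(two["a"]), "at least 2")
})

test_that("Welch t matches published rows and is antisymmetric under group swap", {
  w <- welch_t(28, 35.96, 25.16, 45, 3.04, 3.13)
  expect_equal(round(w$t, 2), 6.89)
  # recomputation from the rounded printed summaries gives 27.52
  expect_lt(abs(w$df - 27.5), 0.05)
  expect_lt(w$p, 0.001)
  swapped <- welch_t(45, 3.04, 3.13, 28, 35.96, 25.16)
  expect_equal(swapped$t, -w$t)
  expect_equal(swapped$df, w$df)
  expect_equal(swapped$p, w$p)
  eq <- welch_t(10, 5, 1, 12, 5, 2)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(welch_t(10, 5, 0, 12, 5, 0), "both SDs")
})

test_that("Cohen's d with pooled SD matches published rows", {
  d1 <- cohens_d_pooled(68, 12.94, 11.02, 41, 5.71, 6.10)
  expect_equal(round(d1$d, 2), 0.76)
  d2 <- cohens_d_pooled(57, 65.52, 31.63, 36, 29.12, 35.01)
  expect_equal(round(d2$d, 2), 1.10)
  expect_equal(cohens_d_pooled(10, 4, 1, 10, 4, 1)$d, 0)
  expect_error(cohens_d_pooled(10, 4, 0, 10, 5, 0), "pooled SD")
})

test_that("the subgroup test holds its nominal size under a null simulation", {
  set.seed(2026)
  n_rep <- 2000
  k <- 10
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    res <- lapply(1:2, function(g) {
      v <- runif(k, 0.02, 0.08)
      y <- rnorm(k, 0, sqrt(v + 0.03))   # common truth, tau2 = 0.03
      pool_random_effects(y, v, method = "DL")
    })
    rej[i] <- subgroup_difference(setNames(res, c("a", "b")))$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
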