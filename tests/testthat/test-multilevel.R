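eff_six <- compute_effects(make_fixture("six_study_multilevel"), r = 0.675)

test_that("REML variance components match a brute-force likelihood lattice", {
  fit <- fit_multilevel(eff_six)
  X <- sapply(levels(droplevels(eff_six$arm_type)),
              function(l) as.numeric(eff_six$arm_type == l))
  up_s <- max(0.05, 2 * fit$sigma2_study + 0.02)
  up_a <- max(0.05, 2 * fit$sigma2_arm + 0.02)
  grid <- oracle_ml_grid(eff_six$smd, eff_six$variance, X, eff_six$study_id,
                         up_s, up_a, step = 1e-3)
  expect_lt(abs(fit$sigma2_study - grid$sigma2_study), 1.5e-3)
  expect_lt(abs(fit$sigma2_arm - grid$sigma2_arm), 1.5e-3)
  # and the optimiser's likelihood is no worse than the lattice's best
  expect_gte(fit$loglik_reml + 1e-8,
             grid$loglik - 0.5 * (fit$k_arms - ncol(X)) * log(2 * pi))
})

test_that("the three-level fit agrees with the independent library implementation", {
  skip_if_not_installed("metafor")
  db <- make_fixture("paper_scale_default")
  eff <- compute_effects(db, r = 0.675)
  fit <- fit_multilevel(eff)
  mf <- metafor::rma.mv(smd ~ 0 + arm_type, V = variance,
                        random = ~ 1 | study_id / arm_id, data = eff,
                        method = "REML")
  expect_equal(unname(fit$coefficients), as.numeric(mf$beta), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(mf$se), tolerance = 1e-6)
  expect_equal(fit$sigma2_study, mf$sigma2[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_arm, mf$sigma2[2], tolerance = 1e-5)
})

test_that("with one arm per study and no arm variance the model collapses to RE pooling", {
  one <- eff_six[!duplicated(eff_six$study_id) & eff_six$role == "active", ]
  one <- droplevels(one)
  # single arm type so the design is a lone indicator column
  one$arm_type <- factor("medication_active", levels = "medication_active")
  fit <- fit_multilevel(one, sigma2_arm = 0)
  ref <- pool_random_effects(one$smd, one$variance, method = "REML")
  expect_equal(unname(fit$coefficients), ref$pooled, tolerance = 1e-6)
  expect_equal(unname(fit$se), ref$se, tolerance = 1e-6)
  expect_equal(fit$sigma2_study, ref$tau2, tolerance = 1e-5)
})

test_that("with both variance components fixed at zero the fit is closed-form WLS", {
  fit <- fit_multilevel(eff_six, sigma2_study = 0, sigma2_arm = 0)
  X <- sapply(levels(droplevels(eff_six$arm_type)),
              function(l) as.numeric(eff_six$arm_type == l))
  w <- 1 / eff_six$variance
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * eff_six$smd))
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-10)
})

test_that("the REML objective is parameterisation invariant", {
  fit1 <- fit_multilevel(eff_six)
  lev <- levels(droplevels(eff_six$arm_type))
  X1 <- sapply(lev, function(l) as.numeric(eff_six$arm_type == l))
  X2 <- cbind(intercept = 1, X1[, -1, drop = FALSE])  # intercept + contrasts
  fit2 <- fit_multilevel(eff_six, design = X2)
  expect_equal(fit2$loglik_reml, fit1$loglik_reml, tolerance = 1e-8)
  expect_equal(fit2$sigma2_study, fit1$sigma2_study, tolerance = 1e-5)
  # at common variance components the equivalence is exact: fitted values and
  # the contrast between two arm types agree to 1e-8
  g1 <- fit_multilevel(eff_six, design = X1, sigma2_study = fit1$sigma2_study,
                       sigma2_arm = fit1$sigma2_arm)
  g2 <- fit_multilevel(eff_six, design = X2, sigma2_study = fit1$sigma2_study,
                       sigma2_arm = fit1$sigma2_arm)
  expect_equal(as.numeric(X2 %*% g2$coefficients),
               as.numeric(X1 %*% g1$coefficients), tolerance = 1e-8)
  c1 <- arm_type_contrast(g1, lev[2], lev[1])
  c2 <- list(difference = unname(g2$coefficients[lev[2]]),
             se = sqrt(g2$vcov[lev[2], lev[2]]))
  expect_equal(c2$difference, c1$difference, tolerance = 1e-8)
  expect_equal(c2$se, c1$se, tolerance = 1e-8)
})

test_that("perturbing either variance component away from the optimum lowers the likelihood", {
  db <- make_fixture("paper_scale_default")
  eff <- compute_effects(db, r = 0.675)
  fit <- fit_multilevel(eff)
  ll <- function(s2s, s2a) {
    armcompare:::ml_reml_pieces(s2s, s2a,
                                eff$smd, eff$variance,
                                sapply(levels(eff$arm_type),
                                       function(l) as.numeric(eff$arm_type == l)),
                                eff$study_id)$loglik
  }
  for (f in c(0.9, 1.1)) {
    expect_lte(ll(fit$sigma2_study * f, fit$sigma2_arm), fit$loglik_reml + 1e-9)
    expect_lte(ll(fit$sigma2_study, fit$sigma2_arm * f), fit$loglik_reml + 1e-9)
  }
})

test_that("rank-deficient designs are refused with the collinear columns named", {
  X <- sapply(levels(droplevels(eff_six$arm_type)),
              function(l) as.numeric(eff_six$arm_type == l))
  bad <- cbind(X, dup = X[, 1])
  expect_error(fit_multilevel(eff_six, design = bad), "rank deficient")
})

test_that("arm-type contrasts follow the covariance formula", {
  fit <- fit_multilevel(eff_six)
  a <- "medication_control"; b <- "psychotherapy_control"
  ct <- arm_type_contrast(fit, a, b)
  expect_equal(ct$difference, unname(fit$coefficients[a] - fit$coefficients[b]))
  expect_equal(ct$se, sqrt(fit$vcov[a, a] + fit$vcov[b, b] - 2 * fit$vcov[a, b]))
  expect_equal(ct$z, ct$difference / ct$se)
  same <- arm_type_contrast(fit, a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$z, 0)
  expect_error(arm_type_contrast(fit, a, "nonexistent_arm"), "absent")
})

test_that("a constant baseline moderator is dropped with a warning", {
  eff <- eff_six
  eff$baseline_fraction <- 0.4
  expect_warning(fit <- rtm_adjusted_fit(eff), "constant")
  ref <- fit_multilevel(eff_six)
  expect_equal(fit$coefficients, ref$coefficients, tolerance = 1e-8)
  eff$baseline_fraction[1] <- NA
  expect_error(rtm_adjusted_fit(eff), "missing")
})

test_that("the adjustment recovers a generating baseline-severity slope", {
  db <- make_fixture("rtm_slope")   # change depends on baseline, slope -2
  eff <- compute_effects(db, r = 0.675)
  fit <- rtm_adjusted_fit(eff)
  b <- fit$coefficients[["baseline_centered"]]
  se <- fit$se[["baseline_centered"]]
  expect_true(b - 1.96 * se <= -2 && -2 <= b + 1.96 * se)
  # adjustment shifts the control contrast but keeps it significant here
  ct <- arm_type_contrast(fit, "psychotherapy_control", "medication_control")
  expect_gt(ct$z, 1.645)
})

test_that("a permuted baseline moderator covers zero at the nominal rate", {
  params <- generator_params(n_psychotherapy = 12, n_medication = 12, seed = 31L)
  eff <- compute_effects(generate_database(params), r = 0.675)
  set.seed(99)
  covers <- vapply(seq_len(200), function(i) {
    perm <- sample(eff$baseline_fraction)
    fit <- rtm_adjusted_fit(eff, baselines = perm)
    b <- fit$coefficients[["baseline_centered"]]
    se <- fit$se[["baseline_centered"]]
    b - 1.96 * se <= 0 && 0 <= b + 1.96 * se
  }, logical(1))
  expect_gte(mean(covers), 0.9)
})
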