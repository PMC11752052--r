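test_that("dispersion imputation follows the recovery chain rule by rule", {
  # SD from SE: sd = se * sqrt(n)
  a <- make_arm(post_sd = NA_real_, se_reported = 1, n = 100)
  imp <- impute_dispersion(a, r = 0.5)
  expect_equal(imp$change_sd, 10)
  expect_equal(imp$flags, "sd_from_se")
  # SD from 95% CI: sd = ((hi - lo) / 3.92) * sqrt(n)
  a <- make_arm(post_sd = NA_real_, ci_low = -1.96, ci_high = 1.96, n = 25)
  imp <- impute_dispersion(a, r = 0.5)
  expect_equal(imp$change_sd, 5)
  expect_equal(imp$flags, "sd_from_ci")
  # SE from t, then SD from SE
  a <- make_arm(post_sd = NA_real_, change_mean = -6, t_reported = -3, n = 36)
  imp <- impute_dispersion(a, r = 0.5)
  expect_equal(imp$change_sd, 2 * 6)  # se = 6/3 = 2, sd = 2 * sqrt(36)
  expect_equal(imp$flags, "sd_from_t")
  # |t| recovered from a two-sided p, then the t rule
  n <- 50; t_true <- 2.5
  p <- 2 * pt(t_true, df = n - 1, lower.tail = FALSE)
  a <- make_arm(post_sd = NA_real_, change_mean = -5, p_reported = p, n = n)
  imp <- impute_dispersion(a, r = 0.5)
  expect_equal(imp$change_sd, (5 / t_true) * sqrt(n), tolerance = 1e-10)
  expect_setequal(imp$flags, c("sd_from_p", "sd_from_t"))
  # change SD from pre/post SDs and r
  a <- make_arm(baseline_sd = 10, post_sd = 10, change_sd = NA_real_)
  imp <- impute_dispersion(a, r = 0.5)
  expect_equal(imp$change_sd, 10)  # sqrt(100 + 100 - 100)
  expect_equal(imp$flags, "change_sd_from_r")
  # a reported change SD wins over everything
  a <- make_arm(change_sd = 7, se_reported = 1)
  expect_equal(impute_dispersion(a, r = 0.5),
               list(change_sd = 7, flags = character(0)))
})

test_that("imputation failures raise named errors", {
  a <- make_arm(baseline_sd = NA_real_, post_sd = NA_real_, arm_id = "bad1")
  expect_error(impute_dispersion(a, r = 0.5), "bad1")
  a <- make_arm(post_sd = NA_real_, change_mean = -5, t_reported = 0)
  expect_error(impute_dispersion(a, r = 0.5), "degenerate")
})

test_that("the pre-post SMD matches its defining formulas", {
  # worked example: baseline 60 (SD 10), post 41, n = 100, r = 0.675
  a <- make_arm(baseline_mean = 60, baseline_sd = 10, post_mean = 41, n = 100)
  e <- prepost_smd(a, r = 0.675, hedges = FALSE)
  expect_equal(e$smd, -1.9, tolerance = 1e-12)
  expect_equal(e$variance, 2 * 0.325 / 100 + 3.61 / 200, tolerance = 1e-12)
  # no change: smd 0, variance 2(1-r)/n
  a <- make_arm(post_mean = 60)
  e <- prepost_smd(a, r = 0.6, hedges = FALSE)
  expect_equal(e$smd, 0)
  expect_equal(e$variance, 2 * 0.4 / 100)
  # Hedges factor scales estimate by J and variance by J^2
  a <- make_arm(baseline_mean = 60, baseline_sd = 10, post_mean = 41, n = 100)
  raw <- prepost_smd(a, r = 0.675, hedges = FALSE)
  cor <- prepost_smd(a, r = 0.675, hedges = TRUE)
  j <- 1 - 3 / (4 * 99 - 1)
  expect_equal(cor$smd, j * raw$smd)
  expect_equal(cor$variance, j^2 * raw$variance)
  expect_error(prepost_smd(make_arm(n = 1), r = 0.5), "n must be >= 2")
  expect_error(prepost_smd(make_arm(baseline_sd = NA_real_), r = 0.5),
               "baseline_sd")
})

test_that("the point estimate is r-free and its variance strictly decreases in r", {
  a <- make_arm(baseline_mean = 55, baseline_sd = 8, post_mean = 47, n = 40)
  rs <- seq(0.45, 0.9, by = 0.05)
  out <- vapply(rs, function(r) {
    e <- prepost_smd(a, r = r)
    c(e$smd, e$variance)
  }, numeric(2))
  expect_equal(diff(out[1, ]), rep(0, length(rs) - 1))
  expect_true(all(diff(out[2, ]) < 0))
})

test_that("the SMD is invariant under affine rescaling of the outcome scale", {
  a <- make_arm(baseline_mean = 60, baseline_sd = 10, post_mean = 48,
                post_sd = 11, n = 60)
  e0 <- prepost_smd(a, r = 0.7)
  for (tr in list(c(2.5, 0), c(1, 30), c(0.4, -7))) {
    b <- a
    for (f in c("baseline_mean", "post_mean")) b[[f]] <- tr[1] * b[[f]] + tr[2]
    for (f in c("baseline_sd", "post_sd")) b[[f]] <- tr[1] * b[[f]]
    e1 <- prepost_smd(b, r = 0.7)
    expect_equal(e1$smd, e0$smd, tolerance = 1e-12)
    expect_equal(e1$variance, e0$variance, tolerance = 1e-12)
  }
})

test_that("Hedges correction lies in (0,1) and tends to 1", {
  n <- c(5, 10, 50, 1000, 1e6)
  j <- 1 - 3 / (4 * (n - 1) - 1)
  expect_true(all(j > 0 & j < 1))
  expect_true(all(diff(j) > 0))
  expect_lt(1 - j[length(j)], 1e-5)
})

test_that("compute_effects labels arm types and flags imputation provenance", {
  db <- make_fixture("paper_scale_default")
  eff <- compute_effects(db, r = 0.675)
  expect_equal(nrow(eff), nrow(db$arms))
  mod <- db$studies$modality[match(eff$study_id, db$studies$study_id)]
  expect_equal(as.character(eff$arm_type), paste(mod, eff$role, sep = "_"))
  # arms that reported post SDs need no imputation flags
  expect_true(all(eff$imputation_flags[!is.na(db$arms$post_sd)] == ""))
  # arms reporting change statistics through an SE carry the se flag
  via_se <- !is.na(db$arms$se_reported)
  expect_true(any(via_se))
  expect_true(all(eff$imputation_flags[via_se] == "sd_from_se"))
  # the change-SD standardizer is r-dependent in general but still finite
  eff2 <- compute_effects(db, r = 0.675, standardizer = "change")
  expect_true(all(is.finite(eff2$smd) & eff2$variance > 0))
})
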