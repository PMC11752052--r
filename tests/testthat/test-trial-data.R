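test_that("a minimal two-arm medication study loads with correct counts", {
  db <- trial_database(
    make_study(),
    rbind(make_arm(arm_id = "a1", role = "active"),
          make_arm(arm_id = "c1", role = "control")))
  expect_s3_class(db, "trial_db")
  expect_equal(db$report$n_studies, 1L)
  expect_equal(db$report$n_arms, 2L)
  expect_equal(unname(db$report$arms_by_type[["medication_active"]]), 1L)
  expect_equal(unname(db$report$arms_by_type[["medication_control"]]), 1L)
})

test_that("empty input files yield an empty database with a warning", {
  d <- withr::local_tempdir()
  writeLines(paste(armcompare:::ARM_COLUMNS, collapse = ","),
             file.path(d, "arms.csv"))
  writeLines(paste(armcompare:::STUDY_COLUMNS, collapse = ","),
             file.path(d, "studies.csv"))
  expect_warning(
    db <- load_trials(file.path(d, "arms.csv"), file.path(d, "studies.csv")),
    "empty")
  expect_equal(db$report$n_studies, 0L)
})

test_that("schema violations are rejected with informative errors", {
  st <- make_study()
  arms2 <- rbind(make_arm(arm_id = "a1"), make_arm(arm_id = "c1", role = "control"))
  expect_error(trial_database(make_study(modality = "homeopathy"), arms2),
               "unknown modality")
  bad <- arms2; bad$arm_id <- "a1"
  expect_error(trial_database(st, bad), "duplicate")
  bad <- arms2; bad$scale <- "BDI"
  expect_error(trial_database(st, bad), "unregistered scale")
  bad <- arms2; bad$control_type[1] <- "waitlist"
  expect_error(trial_database(st, bad), "iff")
  expect_error(
    trial_database(make_study(modality = "psychotherapy"), arms2),
    "pill_placebo")
  bad <- arms2; bad$post_mean <- NA_real_
  expect_error(trial_database(st, bad), "neither post_mean nor change_mean")
  bad <- arms2; bad$baseline_sd[1] <- 0
  expect_error(trial_database(st, bad), "baseline_sd")
})

test_that("a synthetic database round-trips through save/load value-exactly", {
  db <- make_fixture("six_study_multilevel")
  d <- withr::local_tempdir()
  save_trials(db, d)
  db2 <- load_trials(file.path(d, "arms.csv"), file.path(d, "studies.csv"),
                     file.path(d, "scales.csv"))
  expect_equal(db2$arms, db$arms)
  expect_equal(db2$studies, db$studies)
  expect_equal(db2$scales, db$scales)
  expect_true(file.exists(file.path(d, "truth.json")))
})

test_that("waitlist exclusion removes whole waitlist-only studies, keeps mixed ones", {
  studies <- rbind(make_study("W1", "psychotherapy"),
                   make_study("M1", "psychotherapy"),
                   make_study("K1", "psychotherapy"))
  arms <- rbind(
    make_arm("W1", "a1"), make_arm("W1", "c1", "control", "waitlist"),
    make_arm("M1", "a1"), make_arm("M1", "c1", "control", "waitlist"),
    make_arm("M1", "c2", "control", "tau"),
    make_arm("K1", "a1"), make_arm("K1", "c1", "control", "other"))
  arms$control_type[arms$role == "active"] <- "none"
  db <- trial_database(studies, arms)
  out <- apply_filter(db, filter_spec(exclude_waitlist = TRUE))
  expect_setequal(out$studies$study_id, c("M1", "K1"))
  # mixed-control study keeps only its non-waitlist control
  expect_setequal(out$arms$arm_id[out$arms$study_id == "M1"], c("a1", "c2"))
  # no-op on a database without waitlist studies
  expect_equal(apply_filter(out, filter_spec(exclude_waitlist = TRUE)), out)
})

test_that("the variance filter applies strict inequality at the reference correlation", {
  # hand-enumerated variances at r = 0.675 with the Hedges factor:
  # v = J^2 * (2 * 0.325 / n + d^2 / (2 n))
  arms <- rbind(
    make_arm("S1", "a1", n = 80, baseline_mean = 60, baseline_sd = 10, post_mean = 58),
    make_arm("S1", "a2", n = 33, baseline_mean = 60, baseline_sd = 10, post_mean = 58),
    make_arm("S1", "a3", n = 13, baseline_mean = 60, baseline_sd = 10, post_mean = 58))
  v_hand <- sapply(c(80, 33, 13), function(n) {
    j <- 1 - 3 / (4 * (n - 1) - 1)
    d <- (58 - 60) / 10
    j^2 * (2 * (1 - 0.675) / n + d^2 / (2 * n))
  })
  expect_true(v_hand[1] < v_hand[2] && v_hand[2] < v_hand[3])
  db <- trial_database(make_study("S1"), arms)
  out <- apply_filter(db, filter_spec(max_effect_variance = 0.02))
  expect_setequal(out$arms$arm_id, arms$arm_id[v_hand < 0.02])
  # strict inequality: an arm sitting exactly at the threshold is excluded
  at_threshold <- apply_filter(db, filter_spec(max_effect_variance = v_hand[2]))
  expect_setequal(at_threshold$arms$arm_id, "a1")
})

test_that("filters are idempotent and commute", {
  db <- make_fixture("paper_scale_default")
  specs <- list(w = filter_spec(exclude_waitlist = TRUE),
                s = filter_spec(exclude_subclinical = TRUE),
                v = filter_spec(max_effect_variance = 0.02),
                p = filter_spec(require_post_sd = TRUE))
  for (sp in specs) {
    once <- apply_filter(db, sp)
    expect_equal(apply_filter(once, sp), once)
  }
  ab <- apply_filter(apply_filter(db, specs$w), specs$s)
  ba <- apply_filter(apply_filter(db, specs$s), specs$w)
  expect_equal(ab$arms, ba$arms)
  expect_equal(ab$studies, ba$studies)
  # conjunction in one spec equals sequential application
  both <- apply_filter(db, filter_spec(exclude_waitlist = TRUE,
                                       exclude_subclinical = TRUE))
  expect_equal(both$arms, ab$arms)
})

test_that("unknown filter criteria are rejected", {
  expect_error(filter_spec(exclude_waitlists = TRUE), "unused argument")
})
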