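#' Published reference summary tables
#'
#' Group-level summary statistics published for the 92-trial evidence base:
#' the session-intensity comparison of psychotherapy active vs control arms
#' (per-variable available-case K, mean, SD) and the per-modality trial-site
#' summaries (K, mean, SD, number of multisite trials). These are inputs for
#' recomputing the corresponding test statistics from summaries alone.
#'
#' @return A list with data frames `intensity` (columns `variable, group, k,
#'   mean, sd`) and `sites` (columns `modality, k, mean, sd, n_multisite`).
#' @export
reference_summaries <- function() {
  dir <- system.file("extdata", package = "armcompare")
  list(
    intensity = utils::read.csv(file.path(dir, "reference_intensity.csv"),
                                stringsAsFactors = FALSE),
    sites = utils::read.csv(file.path(dir, "reference_sites.csv"),
                            stringsAsFactors = FALSE)
  )
}

study_characteristics <- function(db) {
  st <- db$studies
  arms <- db$arms
  sc <- db$scales[match(arms$scale, db$scales$name), , drop = FALSE]
  range <- sc$max_score - sc$min_score
  frac <- (arms$baseline_mean - sc$min_score) / range
  frac_sd <- arms$baseline_sd / range
  w <- arms$n
  f <- factor(arms$study_id, levels = st$study_id)
  st$severity <- as.numeric(tapply(frac * w, f, sum) / tapply(w, f, sum))
  st$severity_sd <- as.numeric(tapply(frac_sd * w, f, sum) / tapply(w, f, sum))
  st
}

pool_characteristic <- function(st, characteristic, method) {
  y <- switch(characteristic,
    severity = st$severity,
    percent_female = st$percent_female,
    age = st$mean_age)
  v <- switch(characteristic,
    severity = (st$severity_sd / sqrt(st$n_total))^2,
    percent_female = {
      pr <- st$percent_female / 100
      100^2 * pr * (1 - pr) / st$n_total
    },
    age = (st$sd_age / sqrt(st$n_total))^2)
  ok <- !is.na(y) & !is.na(v) & v > 0
  if (sum(ok) < 2) return(NULL)
  pool_random_effects(y[ok], v[ok], method = method)
}

#' Baseline-comparability meta-analyses
#'
#' For each sample characteristic (baseline severity as a fraction of the
#' scale range, percent female, mean age) and each analysis variant (overall,
#' excluding subclinical studies, excluding waitlist-controlled studies),
#' pools the study-level values per modality by random-effects meta-analysis
#' and tests the modality difference with the between-subgroups Q test.
#' Severity uses `se = sd / sqrt(n)` on the fraction metric (the study's
#' arm-size-weighted baseline SD divided by the scale range); percent female
#' uses the binomial variance `100^2 p (1 - p) / n`; age uses
#' `se = sd_age / sqrt(n)`. All-female studies are excluded from the sex
#' analysis by default. A subgroup with fewer than 2 usable studies is
#' reported as unavailable rather than raising an error.
#'
#' @param db A `"trial_db"`.
#' @param method tau^2 estimator, `"REML"` (default) or `"DL"`.
#' @param exclude_all_female Exclude `percent_female == 100` studies from the
#'   sex analysis (default `TRUE`).
#' @return A data frame of class `"table1"` with one row per characteristic x
#'   variant x modality: `k`, `mean`, `se`, `ci_low`, `ci_high`, `tau2` and
#'   the shared subgroup-difference `p_subgroup`.
#' @export
compare_baseline_characteristics <- function(db, method = "REML",
                                             exclude_all_female = TRUE) {
  variants <- list(
    overall = filter_spec(),
    excl_subclinical = filter_spec(exclude_subclinical = TRUE),
    excl_waitlist = filter_spec(exclude_waitlist = TRUE))
  rows <- list()
  for (vn in names(variants)) {
    dbv <- apply_filter(db, variants[[vn]])
    for (ch in c("severity", "percent_female", "age")) {
      dbc <- dbv
      if (ch == "percent_female" && exclude_all_female) {
        dbc <- apply_filter(dbv, filter_spec(all_female_excluded = TRUE))
      }
      st <- study_characteristics(dbc)
      res <- lapply(split(st, st$modality), pool_characteristic,
                    characteristic = ch, method = method)
      res <- res[!vapply(res, is.null, logical(1))]
      p <- if (length(res) >= 2) subgroup_difference(res)$p else NA_real_
      for (mod in MODALITIES) {
        r <- res[[mod]]
        rows[[length(rows) + 1L]] <- data.frame(
          characteristic = ch, variant = vn, subgroup = mod,
          k = if (is.null(r)) NA_integer_ else r$k,
          mean = if (is.null(r)) NA_real_ else r$pooled,
          se = if (is.null(r)) NA_real_ else r$se,
          ci_low = if (is.null(r)) NA_real_ else r$ci_low,
          ci_high = if (is.null(r)) NA_real_ else r$ci_high,
          tau2 = if (is.null(r)) NA_real_ else r$tau2,
          p_subgroup = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("table1", "data.frame")
  out
}

#' Compare the number of trial sites between modalities
#'
#' Welch t-test on per-study site counts (medication vs psychotherapy) plus
#' the proportion of multisite trials (`n_sites > 1`) per modality among
#' studies reporting site counts.
#'
#' @param db A `"trial_db"`.
#' @return A list of class `"sites_comparison"`: `comparison` (a
#'   [welch_t()] result, or `NULL` with `degenerate = TRUE` when both
#'   modalities have zero variance in site counts) and `multisite` (data
#'   frame with `modality`, `k`, `n_multisite`, `proportion`).
#' @export
compare_sites <- function(db) {
  st <- db$studies[!is.na(db$studies$n_sites), , drop = FALSE]
  ks <- table(factor(st$modality, levels = MODALITIES))
  if (any(ks < 2)) {
    stop("need n_sites for >= 2 studies per modality (have ",
         paste(sprintf("%s=%d", names(ks), ks), collapse = ", "), ")",
         call. = FALSE)
  }
  s <- split(st$n_sites, factor(st$modality, levels = MODALITIES))
  multisite <- data.frame(
    modality = MODALITIES,
    k = as.integer(ks),
    n_multisite = vapply(s, function(x) sum(x > 1), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  multisite$proportion <- multisite$n_multisite / multisite$k
  cmp <- tryCatch(
    welch_t(length(s$medication), mean(s$medication), stats::sd(s$medication),
            length(s$psychotherapy), mean(s$psychotherapy),
            stats::sd(s$psychotherapy)),
    error = function(e) NULL)
  structure(list(comparison = cmp, multisite = multisite,
                 degenerate = is.null(cmp)),
            class = "sites_comparison")
}

#' @export
print.sites_comparison <- function(x, ...) {
  cat("<sites_comparison>\n")
  print(x$multisite)
  if (x$degenerate) cat("  t-test degenerate (no variance in site counts)\n")
  else print(x$comparison)
  invisible(x)
}

INTENSITY_VARS <- c("n_sessions", "sessions_per_week", "session_minutes",
                    "total_hours")

#' Compare intensity of psychotherapy active vs control arms
#'
#' For each intensity variable (number of sessions, sessions per week,
#' session length in minutes, total intervention hours), compares the
#' psychotherapy active arms with the psychotherapy control arms by Welch
#' t-test and pooled-SD Cohen's d, using the available cases per variable
#' (control conditions are often poorly described, so the K differs across
#' rows). Significance is evaluated at the Bonferroni-corrected threshold
#' `alpha / bonferroni_m` (0.05 / 4 = 0.0125 by default).
#'
#' @param db A `"trial_db"`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param bonferroni_m Number of comparisons corrected for (default 4).
#' @param exclude_waitlist Run the waitlist-excluded sensitivity variant.
#' @return A data frame of class `"table2"`, one row per variable, with group
#'   summaries, `d` and its CI, `t`, `df`, `p` and `significant`. Variables
#'   with fewer than 2 observations in either group are rows of `NA`s.
#' @export
compare_intensity <- function(db, alpha = 0.05, bonferroni_m = 4,
                              exclude_waitlist = FALSE) {
  if (exclude_waitlist) db <- apply_filter(db, filter_spec(exclude_waitlist = TRUE))
  arms <- db$arms
  modality <- db$studies$modality[match(arms$study_id, db$studies$study_id)]
  arms <- arms[modality == "psychotherapy", , drop = FALSE]
  thr <- alpha / bonferroni_m
  rows <- lapply(INTENSITY_VARS, function(vb) {
    a <- arms[[vb]][arms$role == "active"]
    c_ <- arms[[vb]][arms$role == "control"]
    a <- a[!is.na(a)]; c_ <- c_[!is.na(c_)]
    if (length(a) < 2 || length(c_) < 2) {
      return(data.frame(variable = vb, k_active = length(a),
                        mean_active = NA_real_, sd_active = NA_real_,
                        k_control = length(c_), mean_control = NA_real_,
                        sd_control = NA_real_, d = NA_real_,
                        d_ci_low = NA_real_, d_ci_high = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    w <- welch_t(length(a), mean(a), stats::sd(a),
                 length(c_), mean(c_), stats::sd(c_))
    data.frame(variable = vb, k_active = w$k1, mean_active = w$mean1,
               sd_active = w$sd1, k_control = w$k2, mean_control = w$mean2,
               sd_control = w$sd2, d = w$d, d_ci_low = w$d_ci_low,
               d_ci_high = w$d_ci_high, t = w$t, df = w$df, p = w$p,
               significant = w$p < thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  class(out) <- c("table2", "data.frame")
  out
}

#' Analysis configuration
#'
#' Bundles everything [run_full_analysis()] needs: input paths, the
#' correlation-simulation settings, significance conventions, the output
#' directory and the master seed. With defaults the Bonferroni threshold is
#' `0.05 / 4 = 0.0125`.
#'
#' @param arms_path,studies_path,scales_path Input CSVs (see
#'   [load_trials()]); `scales_path` may be `NULL`.
#' @param out_dir Output directory for report files.
#' @param seed Master seed; every random draw derives from it.
#' @param n_sims Simulated datasets per analysis (default 1000).
#' @param r_low,r_high,draw_mode Correlation-simulation settings (see
#'   [simulation_spec()]).
#' @param alpha,bonferroni_m Significance conventions.
#' @param hedges,standardizer Effect-size options (see [prepost_smd()]).
#' @param r_reference Correlation at which single-fit sections (the
#'   regression-to-the-mean adjustment, the control-arm scatter) are
#'   computed; default 0.675, the midpoint of the simulation range.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(arms_path = NULL, studies_path = NULL,
                            scales_path = NULL, out_dir = "armcompare-output",
                            seed = 1L, n_sims = 1000, r_low = 0.45,
                            r_high = 0.9, draw_mode = "per_dataset",
                            alpha = 0.05, bonferroni_m = 4, hedges = TRUE,
                            standardizer = "baseline", r_reference = 0.675) {
  structure(list(arms_path = arms_path, studies_path = studies_path,
                 scales_path = scales_path, out_dir = out_dir,
                 seed = as.integer(seed), n_sims = as.integer(n_sims),
                 r_low = r_low, r_high = r_high, draw_mode = draw_mode,
                 alpha = alpha, bonferroni_m = bonferroni_m, hedges = hedges,
                 standardizer = standardizer, r_reference = r_reference),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the arguments of [analysis_config()]; missing keys
#' take the defaults.
#'
#' @param path YAML file.
#' @return An `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}

SENSITIVITY_FILTERS <- function() list(
  overall = filter_spec(),
  exclude_waitlist = filter_spec(exclude_waitlist = TRUE),
  exclude_subclinical = filter_spec(exclude_subclinical = TRUE),
  cdrs_only = filter_spec(scale_in = "CDRS-R"),
  hamd_only = filter_spec(scale_in = "HAM-D"),
  variance_below_0.02 = filter_spec(max_effect_variance = 0.02),
  post_sd_reported = filter_spec(require_post_sd = TRUE))

#' Run the complete comparability analysis
#'
#' Executes, in order: data loading; per-arm effect computation; the
#' correlation-uncertainty simulation for the overall database and for each
#' sensitivity filter (waitlist excluded, subclinical excluded, CDRS-R only,
#' HAM-D only, SMD variance below 0.02, post-SD reported); the stability
#' analysis of the control-arm contrast; the regression-to-the-mean-adjusted
#' fit; the baseline-comparability meta-analyses; the trial-sites comparison;
#' and the intensity comparison with its waitlist-excluded variant. Each
#' completed section is written to `config$out_dir` (`table1.csv`,
#' `table2.csv`, `table2_no_waitlist.csv`, `fig2_data.csv`, `fig3_data.csv`,
#' `sensitivity_smds.csv`, `sites.json`, `stability.csv`, `rtm.json`,
#' `run.log`) before the next starts, so a failing section aborts with a
#' section-named error after flushing everything already computed. Outputs
#' are a deterministic function of (config, inputs, seed).
#'
#' @param config An [analysis_config()].
#' @param db Optionally, an already-loaded `"trial_db"` (bypasses the paths).
#' @return Invisibly, a list of class `"report_bundle"` with elements
#'   `table1`, `table2`, `table2_no_waitlist`, `fig2_data`, `fig3_data`,
#'   `sensitivity`, `sites`, `stability`, `rtm`, `db`.
#' @export
run_full_analysis <- function(config, db = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("armcompare run | seed %d | n_sims %d | r in [%g, %g] (%s)",
                         config$seed, config$n_sims, config$r_low,
                         config$r_high, config$draw_mode))
  flush_log <- function() writeLines(log_lines, file.path(out, "run.log"))
  section <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      flush_log()
      stop("section '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  bundle <- list()

  db <- section("load", {
    if (is.null(db)) {
      db <- load_trials(config$arms_path, config$studies_path,
                        config$scales_path)
    }
    db
  })
  log_lines <- c(log_lines,
                 sprintf("loaded %d studies, %d arms", db$report$n_studies,
                         db$report$n_arms))
  bundle$db <- db

  effects <- section("effects", {
    compute_effects(db, r = config$r_reference, hedges = config$hedges,
                    standardizer = config$standardizer)
  })

  filters <- SENSITIVITY_FILTERS()
  sens_rows <- list()
  for (i in seq_along(filters)) {
    fname <- names(filters)[i]
    sim <- section(paste0("simulation_", fname), {
      dbf <- apply_filter(db, filters[[i]])
      spec <- simulation_spec(n_sims = config$n_sims, r_low = config$r_low,
                              r_high = config$r_high,
                              draw_mode = config$draw_mode,
                              seed = config$seed + i)
      run_simulation(dbf, spec, hedges = config$hedges,
                     standardizer = config$standardizer)
    })
    log_lines <- c(log_lines,
                   sprintf("simulation '%s': K studies %d, arms %d, failed %d",
                           fname,
                           length(unique(apply_filter(db, filters[[i]])$studies$study_id)),
                           nrow(apply_filter(db, filters[[i]])$arms),
                           sim$n_failed))
    sens_rows[[fname]] <- cbind(analysis = fname, sim$per_arm_type,
                                stringsAsFactors = FALSE)
    if (fname == "overall") bundle$overall_sim <- sim
  }
  bundle$sensitivity <- do.call(rbind, c(sens_rows, make.row.names = FALSE))
  utils::write.csv(bundle$sensitivity, file.path(out, "sensitivity_smds.csv"),
                   row.names = FALSE)

  bundle$fig2_data <- bundle$overall_sim$per_arm_type
  utils::write.csv(bundle$fig2_data, file.path(out, "fig2_data.csv"),
                   row.names = FALSE)

  bundle$stability <- bundle$overall_sim$stability
  utils::write.csv(
    data.frame(sim_count = seq_along(bundle$stability$cumulative_trace),
               proportion_above = bundle$stability$cumulative_trace),
    file.path(out, "stability.csv"), row.names = FALSE)

  bundle$fig3_data <- section("fig3", {
    ctrl <- effects[effects$role == "control",
                    c("study_id", "arm_id", "arm_type", "n", "smd", "variance")]
    ctrl$weight <- 1 / ctrl$variance
    rownames(ctrl) <- NULL
    ctrl
  })
  utils::write.csv(bundle$fig3_data, file.path(out, "fig3_data.csv"),
                   row.names = FALSE)

  bundle$rtm <- section("rtm", {
    fit <- rtm_adjusted_fit(effects)
    ct <- arm_type_contrast(fit, "psychotherapy_control", "medication_control")
    list(coefficients = as.list(fit$coefficients),
         se = as.list(fit$se),
         sigma2_study = fit$sigma2_study, sigma2_arm = fit$sigma2_arm,
         contrast_psy_minus_med_control = ct)
  })
  jsonlite::write_json(bundle$rtm, file.path(out, "rtm.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  bundle$table1 <- section("table1", compare_baseline_characteristics(db))
  utils::write.csv(bundle$table1, file.path(out, "table1.csv"),
                   row.names = FALSE)

  bundle$sites <- section("sites", compare_sites(db))
  jsonlite::write_json(
    list(multisite = bundle$sites$multisite,
         degenerate = bundle$sites$degenerate,
         comparison = if (bundle$sites$degenerate) NULL else
           unclass(bundle$sites$comparison)),
    file.path(out, "sites.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  bundle$table2 <- section("table2", {
    compare_intensity(db, alpha = config$alpha,
                      bonferroni_m = config$bonferroni_m)
  })
  utils::write.csv(bundle$table2, file.path(out, "table2.csv"),
                   row.names = FALSE)
  bundle$table2_no_waitlist <- section("table2_no_waitlist", {
    compare_intensity(db, alpha = config$alpha,
                      bonferroni_m = config$bonferroni_m,
                      exclude_waitlist = TRUE)
  })
  utils::write.csv(bundle$table2_no_waitlist,
                   file.path(out, "table2_no_waitlist.csv"), row.names = FALSE)

  flush_log()
  class(bundle) <- "report_bundle"
  invisible(bundle)
}
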