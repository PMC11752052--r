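#' Parameters of the synthetic trial-database generator
#'
#' Defaults emulate the structure of the 92-trial youth-depression evidence
#' base the analysis pipeline targets: 53 psychotherapy and 39 medication
#' studies; true within-arm change SMDs of -1.9 for pill placebo and -0.6 for
#' psychotherapy controls (active-arm truths are not published and are
#' assumptions); baseline severity at 0.42 / 0.37 of the scale range; percent
#' female 53.72 / 61.36 with two all-female psychotherapy trials; mean age
#' 13.69 / 14.3; site counts centred at 36 / 3; a 14:28:20
#' waitlist:TAU:other control mix in psychotherapy; session-intensity
#' distributions centred at the published active/control group summaries; and
#' a true pre-post correlation drawn per study from Uniform(0.45, 0.9).
#'
#' @param n_psychotherapy,n_medication Number of studies per modality.
#' @param smd_true Named vector of true arm-type change SMDs.
#' @param sd_study Between-study SD of true SMDs (default 0.3).
#' @param sd_arm Between-arm-within-study SD (default 0.1).
#' @param r_low,r_high Range of the true pre-post correlation.
#' @param severity_mean,severity_sd Study-level baseline severity fraction
#'   distribution, named by modality.
#' @param baseline_sd_frac Population baseline SD as a fraction of the scale
#'   range (default 0.11, typical of clinician-rated depression totals).
#' @param pf_mean,pf_sd Percent-female distribution by modality.
#' @param n_all_female Number of all-female psychotherapy studies (default 2).
#' @param age_mean,age_sd Study mean-age distribution by modality.
#' @param sites_mean,sites_sd Site-count distribution by modality (normal,
#'   rounded, clamped at 1).
#' @param arm_n_median,arm_n_sdlog,arm_n_max Per-arm sample-size distribution
#'   (log-normal, clamped to `[10, arm_n_max]`), median by modality.
#' @param control_mix Psychotherapy control-type probabilities
#'   (waitlist / tau / other).
#' @param p_extra_active,p_extra_control Probability a study contributes a
#'   second active / control arm, by modality.
#' @param p_no_control Probability a medication study is a single-arm
#'   (active-only) partial extraction.
#' @param subclinical_rate Probability a study is flagged subclinical, by
#'   modality.
#' @param intensity Session-intensity distributions for psychotherapy arms:
#'   a list with elements `active` and `control`, each a list of
#'   `c(mean, sd)` for `n_sessions`, `sessions_per_week`, `session_minutes`.
#'   Total hours and weeks are derived (`sessions x minutes / 60`,
#'   `sessions / per_week`).
#' @param p_post_missing Probability an arm reports change statistics instead
#'   of post mean/SD (the dispersion is then given via one of: change SD,
#'   SE, 95% CI, t, or p, chosen at random, exercising the imputation chain).
#' @param p_postsd_missing Probability the post SD alone is missing.
#' @param p_sites_missing,p_female_missing,p_age_missing Study-level
#'   missingness rates by modality.
#' @param p_intensity_missing Probability a non-waitlist psychotherapy arm's
#'   intensity is unreported, by role (waitlist intensity is always missing).
#' @param rtm_slope Linear dependence of the true change SMD on the study's
#'   centered baseline severity fraction (default 0; set to e.g. -2 to build
#'   regression-to-the-mean recovery fixtures).
#' @param seed Integer seed.
#' @return An object of class `"generator_params"` (a validated list).
#' @export
generator_params <- function(
    n_psychotherapy = 53, n_medication = 39,
    smd_true = c(medication_active = -2.3, medication_control = -1.9,
                 psychotherapy_active = -1.3, psychotherapy_control = -0.6),
    sd_study = 0.3, sd_arm = 0.1,
    r_low = 0.45, r_high = 0.9,
    severity_mean = c(medication = 0.42, psychotherapy = 0.37),
    severity_sd = c(medication = 0.06, psychotherapy = 0.12),
    baseline_sd_frac = 0.11,
    pf_mean = c(medication = 53.72, psychotherapy = 61.36),
    pf_sd = c(medication = 12.3, psychotherapy = 16.2),
    n_all_female = 2,
    age_mean = c(medication = 13.69, psychotherapy = 14.3),
    age_sd = c(medication = 1.92, psychotherapy = 2.39),
    sites_mean = c(medication = 36, psychotherapy = 3),
    sites_sd = c(medication = 25, psychotherapy = 3),
    arm_n_median = c(medication = 90, psychotherapy = 40),
    arm_n_sdlog = 0.5, arm_n_max = 400,
    control_mix = c(waitlist = 14, tau = 28, other = 20) / 62,
    p_extra_active = c(medication = 0.23, psychotherapy = 0.26),
    p_extra_control = c(medication = 0, psychotherapy = 0.17),
    p_no_control = 0.08,
    subclinical_rate = c(medication = 0, psychotherapy = 0.17),
    intensity = list(
      active = list(n_sessions = c(12.94, 11.02),
                    sessions_per_week = c(1.28, 0.71),
                    session_minutes = c(65.52, 31.63)),
      control = list(n_sessions = c(5.71, 6.10),
                     sessions_per_week = c(0.58, 0.67),
                     session_minutes = c(29.12, 35.01))),
    p_post_missing = 0.20, p_postsd_missing = 0.15,
    p_sites_missing = c(medication = 0.28, psychotherapy = 0.15),
    p_female_missing = c(medication = 0.28, psychotherapy = 0.04),
    p_age_missing = c(medication = 0.05, psychotherapy = 0.05),
    p_intensity_missing = c(active = 0.05, control = 0.25),
    rtm_slope = 0,
    seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_psychotherapy >= 0, p$n_medication >= 0,
            setequal(names(p$smd_true), ARM_TYPES),
            p$sd_study >= 0, p$sd_arm >= 0,
            p$r_low > 0, p$r_high < 1, p$r_low <= p$r_high,
            p$baseline_sd_frac > 0,
            abs(sum(p$control_mix) - 1) < 1e-8,
            all(unlist(p[grep("^p_", names(p))]) >= 0),
            all(unlist(p[c("p_post_missing", "p_postsd_missing", "p_no_control")]) <= 1))
  structure(p, class = "generator_params")
}

rnorm_clamp <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

sample_sd <- function(sigma, n) {
  sigma * sqrt(stats::rchisq(length(n), df = n - 1) / (n - 1))
}

#' Generate a synthetic trial database
#'
#' Draws a complete per-arm summary-statistics database with the statistical
#' structure the analysis pipeline assumes. For each study, modality-level
#' characteristics (severity fraction, sex mix, age, sites, control types,
#' pre-post correlation) are drawn; each arm receives a true change SMD equal
#' to its arm-type mean plus study- and arm-level random effects (plus an
#' optional baseline-severity slope). Observed summaries follow their exact
#' sampling distributions under normality: sample means are bivariate normal
#' with correlation `r` between baseline and endpoint, and sample SDs follow
#' the scaled chi-square law with `n - 1` df. Missingness masks are then
#' applied, including the replacement of post statistics by change statistics
#' reported through SEs, CIs, t or p values, so the imputation chain is
#' exercised end to end. The pre-post correlation itself is never emitted,
#' matching practice.
#'
#' @param params A [generator_params()].
#' @param seed Optional override of `params$seed`.
#' @return A validated `"trial_db"` with the full generating truth attached
#'   as `attr(db, "truth")` (written as `truth.json` by [save_trials()]).
#' @export
generate_database <- function(params = generator_params(), seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(seed)) seed <- params$seed
  withr_seed(as.integer(seed), generate_database_impl(params, seed))
}

generate_database_impl <- function(p, seed) {
  n_stud <- c(medication = p$n_medication, psychotherapy = p$n_psychotherapy)
  modality <- rep(names(n_stud), n_stud)
  ns <- length(modality)
  study_id <- sprintf("S%03d", seq_len(ns))

  scale_name <- ifelse(stats::runif(ns) < 0.5, "CDRS-R", "HAM-D")
  sc <- default_scales()
  smin <- sc$min_score[match(scale_name, sc$name)]
  srange <- sc$max_score[match(scale_name, sc$name)] - smin

  sev <- rnorm_clamp(ns, p$severity_mean[modality], p$severity_sd[modality],
                     0.05, 0.90)
  pf <- rnorm_clamp(ns, p$pf_mean[modality], p$pf_sd[modality], 0, 99)
  psy_idx <- which(modality == "psychotherapy")
  if (p$n_all_female > 0 && length(psy_idx) >= p$n_all_female) {
    pf[psy_idx[seq_len(p$n_all_female)]] <- 100
  }
  age <- rnorm_clamp(ns, p$age_mean[modality], p$age_sd[modality], 6, 18)
  sd_age <- rnorm_clamp(ns, 1.5, 0.3, 0.5, Inf)
  sites <- pmax(round(stats::rnorm(ns, p$sites_mean[modality],
                                   p$sites_sd[modality])), 1)
  subclinical <- stats::runif(ns) < p$subclinical_rate[modality]
  r_true <- stats::runif(ns, p$r_low, p$r_high)
  u_study <- stats::rnorm(ns, 0, p$sd_study)

  # arm layout
  n_active <- 1L + (stats::runif(ns) < p$p_extra_active[modality])
  n_control <- 1L + (stats::runif(ns) < p$p_extra_control[modality])
  no_ctrl <- modality == "medication" & stats::runif(ns) < p$p_no_control
  n_control[no_ctrl] <- 0L

  j <- rep(seq_len(ns), n_active + n_control)
  role <- unlist(lapply(seq_len(ns), function(i) {
    c(rep("active", n_active[i]), rep("control", n_control[i]))
  }), use.names = FALSE)
  na_arms <- length(j)

  control_type <- rep("none", na_arms)
  is_ctrl <- role == "control"
  med_ctrl <- is_ctrl & modality[j] == "medication"
  control_type[med_ctrl] <- "pill_placebo"
  psy_ctrl <- is_ctrl & modality[j] == "psychotherapy"
  control_type[psy_ctrl] <- sample(names(p$control_mix), sum(psy_ctrl),
                                   replace = TRUE, prob = p$control_mix)

  arm_type <- paste(modality[j], role, sep = "_")
  n <- round(pmin(pmax(
    stats::rlnorm(na_arms, log(p$arm_n_median[modality[j]]), p$arm_n_sdlog),
    10), p$arm_n_max))

  sev_centered <- sev - p$severity_mean[modality]
  smd_true <- p$smd_true[arm_type] + u_study[j] +
    stats::rnorm(na_arms, 0, p$sd_arm) + p$rtm_slope * sev_centered[j]

  sigma <- p$baseline_sd_frac * srange[j]
  m1 <- smin[j] + sev[j] * srange[j]
  m2 <- m1 + smd_true * sigma
  r <- r_true[j]

  z1 <- stats::rnorm(na_arms)
  z2 <- stats::rnorm(na_arms)
  pre_mean <- m1 + sigma / sqrt(n) * z1
  post_mean <- m2 + sigma / sqrt(n) * (r * z1 + sqrt(1 - r^2) * z2)
  pre_sd <- sample_sd(sigma, n)
  post_sd <- sample_sd(sigma, n)
  change_mean <- post_mean - pre_mean
  change_sd <- sample_sd(sigma * sqrt(2 * (1 - r)), n)

  arms <- data.frame(
    study_id = study_id[j],
    arm_id = character(na_arms),
    role = role, control_type = control_type, n = n, scale = scale_name[j],
    baseline_mean = pre_mean, baseline_sd = pre_sd,
    post_mean = post_mean, post_sd = post_sd,
    change_mean = NA_real_, change_sd = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, se_reported = NA_real_,
    t_reported = NA_real_, p_reported = NA_real_,
    n_sessions = NA_real_, session_minutes = NA_real_,
    sessions_per_week = NA_real_, total_weeks = NA_real_,
    total_hours = NA_real_,
    stringsAsFactors = FALSE)
  arms$arm_id <- unlist(lapply(split(role, factor(j, levels = seq_len(ns))),
                               function(rr) {
    paste0(substr(rr, 1, 1), stats::ave(seq_along(rr), rr, FUN = seq_along))
  }), use.names = FALSE)

  # missingness: some arms report change statistics instead of post scores
  u <- stats::runif(na_arms)
  route_arms <- u < p$p_post_missing
  # arms missing only the post SD still report the change SD, as real trials
  # that omit endpoint dispersion typically give change-score statistics
  sd_only <- !route_arms & u < p$p_post_missing + p$p_postsd_missing
  arms$post_sd[sd_only] <- NA_real_
  arms$change_sd[sd_only] <- change_sd[sd_only]
  if (any(route_arms)) {
    route <- sample(c("change_sd", "se", "ci", "t", "p"), sum(route_arms),
                    replace = TRUE)
    idx <- which(route_arms)
    # a p value too small to print cannot be inverted; report t instead
    p_implied <- 2 * stats::pt(abs(change_mean[idx] / (change_sd[idx] / sqrt(n[idx]))),
                               df = n[idx] - 1, lower.tail = FALSE)
    route[route == "p" & p_implied < 1e-10] <- "t"
    arms$post_mean[idx] <- NA_real_
    arms$post_sd[idx] <- NA_real_
    arms$change_mean[idx] <- change_mean[idx]
    se <- change_sd[idx] / sqrt(n[idx])
    tt <- change_mean[idx] / se
    arms$change_sd[idx[route == "change_sd"]] <- change_sd[idx][route == "change_sd"]
    arms$se_reported[idx[route == "se"]] <- se[route == "se"]
    arms$ci_low[idx[route == "ci"]] <- (change_mean[idx] - 1.96 * se)[route == "ci"]
    arms$ci_high[idx[route == "ci"]] <- (change_mean[idx] + 1.96 * se)[route == "ci"]
    arms$t_reported[idx[route == "t"]] <- tt[route == "t"]
    pp <- 2 * stats::pt(abs(tt), df = n[idx] - 1, lower.tail = FALSE)
    pp <- pmax(pmin(pp, 1 - 1e-12), 1e-300)
    arms$p_reported[idx[route == "p"]] <- pp[route == "p"]
  }

  # session intensity for psychotherapy arms
  psy_arm <- modality[j] == "psychotherapy"
  for (rl in c("active", "control")) {
    sel <- which(psy_arm & role == rl & control_type != "waitlist")
    if (!length(sel)) next
    keep <- sel[stats::runif(length(sel)) >= p$p_intensity_missing[[rl]]]
    if (!length(keep)) next
    ip <- p$intensity[[rl]]
    nses <- pmax(round(stats::rnorm(length(keep), ip$n_sessions[1],
                                    ip$n_sessions[2])), 1)
    spw <- rnorm_clamp(length(keep), ip$sessions_per_week[1],
                       ip$sessions_per_week[2], 0.1, Inf)
    mins <- rnorm_clamp(length(keep), ip$session_minutes[1],
                        ip$session_minutes[2], 5, Inf)
    arms$n_sessions[keep] <- nses
    arms$sessions_per_week[keep] <- round(spw, 2)
    arms$session_minutes[keep] <- round(mins)
    arms$total_weeks[keep] <- round(nses / spw, 1)
    arms$total_hours[keep] <- round(nses * round(mins) / 60, 2)
  }

  n_total <- as.integer(tapply(n, factor(study_id[j], levels = study_id), sum))
  studies <- data.frame(
    study_id = study_id, modality = modality,
    n_sites = ifelse(stats::runif(ns) < p$p_sites_missing[modality],
                     NA_real_, sites),
    subclinical = subclinical,
    percent_female = ifelse(pf < 100 &
                              stats::runif(ns) < p$p_female_missing[modality],
                            NA_real_, round(pf, 2)),
    mean_age = ifelse(stats::runif(ns) < p$p_age_missing[modality],
                      NA_real_, round(age, 2)),
    sd_age = round(sd_age, 2),
    n_total = n_total,
    stringsAsFactors = FALSE)
  studies$sd_age[is.na(studies$mean_age)] <- NA_real_

  num <- c("baseline_mean", "baseline_sd", "post_mean", "post_sd",
           "change_mean", "change_sd", "ci_low", "ci_high", "se_reported",
           "t_reported")
  for (cl in num) arms[[cl]] <- round(arms[[cl]], 4)
  arms$p_reported <- signif(arms$p_reported, 6)

  db <- suppressWarnings(trial_database(studies, arms, default_scales()))
  truth <- unclass(p)
  truth$seed_used <- as.integer(seed)
  truth$arm_truth <- data.frame(study_id = study_id[j], arm_id = arms$arm_id,
                                arm_type = arm_type, smd_true = smd_true,
                                r_true = r, stringsAsFactors = FALSE)
  attr(db, "truth") <- truth
  db
}

#' Named deterministic fixtures
#'
#' Fixed-seed databases used across the test suites:
#' `minimal_two_arm` (one medication study, two arms, hand-written values),
#' `six_study_multilevel` (6 studies / 12 arms, small enough for brute-force
#' likelihood checks), `paper_scale_default` (the full 92-study default
#' generator), `null_no_modality_difference` (both modalities share every
#' generating parameter), and `rtm_slope` (change generated with an explicit
#' baseline-severity slope of -2 per fraction unit).
#'
#' @param name Fixture name.
#' @return A `"trial_db"`.
#' @export
make_fixture <- function(name = c("minimal_two_arm", "six_study_multilevel",
                                  "paper_scale_default",
                                  "null_no_modality_difference", "rtm_slope")) {
  name <- match.arg(name)
  switch(name,
    minimal_two_arm = {
      studies <- data.frame(study_id = "S001", modality = "medication",
                            n_sites = 12, subclinical = FALSE,
                            percent_female = 55, mean_age = 14.2, sd_age = 1.5,
                            n_total = 180, stringsAsFactors = FALSE)
      arms <- empty_arm_table()[0, ]
      arms <- rbind(arms, data.frame(
        study_id = "S001", arm_id = c("a1", "c1"),
        role = c("active", "control"),
        control_type = c("none", "pill_placebo"), n = c(90, 90),
        scale = "CDRS-R",
        baseline_mean = c(60, 60.5), baseline_sd = c(10, 10.4),
        post_mean = c(37, 41.5), post_sd = c(11, 10.8),
        change_mean = NA_real_, change_sd = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, se_reported = NA_real_, t_reported = NA_real_,
        p_reported = NA_real_, n_sessions = NA_real_,
        session_minutes = NA_real_, sessions_per_week = NA_real_,
        total_weeks = NA_real_, total_hours = NA_real_,
        stringsAsFactors = FALSE))
      trial_database(studies, arms)
    },
    six_study_multilevel = generate_database(
      generator_params(n_psychotherapy = 3, n_medication = 3,
                       p_extra_active = c(medication = 0, psychotherapy = 0),
                       p_extra_control = c(medication = 0, psychotherapy = 0),
                       p_no_control = 0, p_post_missing = 0,
                       p_postsd_missing = 0, n_all_female = 0,
                       seed = 11L)),
    paper_scale_default = generate_database(generator_params(seed = 42L)),
    null_no_modality_difference = generate_database(null_modality_params(seed = 7L)),
    rtm_slope = generate_database(
      generator_params(rtm_slope = -2, seed = 23L))
  )
}

# both modalities share every generating parameter (control-type labels aside)
null_modality_params <- function(seed = 7L, ...) {
  generator_params(
    smd_true = c(medication_active = -1.6, medication_control = -1.0,
                 psychotherapy_active = -1.6, psychotherapy_control = -1.0),
    severity_mean = c(medication = 0.40, psychotherapy = 0.40),
    severity_sd = c(medication = 0.10, psychotherapy = 0.10),
    pf_mean = c(medication = 57, psychotherapy = 57),
    pf_sd = c(medication = 14, psychotherapy = 14),
    n_all_female = 0,
    age_mean = c(medication = 14, psychotherapy = 14),
    age_sd = c(medication = 2.2, psychotherapy = 2.2),
    sites_mean = c(medication = 10, psychotherapy = 10),
    sites_sd = c(medication = 8, psychotherapy = 8),
    arm_n_median = c(medication = 60, psychotherapy = 60),
    p_extra_active = c(medication = 0.25, psychotherapy = 0.25),
    p_extra_control = c(medication = 0.1, psychotherapy = 0.1),
    p_no_control = 0,
    subclinical_rate = c(medication = 0.1, psychotherapy = 0.1),
    p_sites_missing = c(medication = 0.1, psychotherapy = 0.1),
    p_female_missing = c(medication = 0.1, psychotherapy = 0.1),
    seed = seed, ...)
}
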