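ARM_TYPES <- c("medication_active", "medication_control",
               "psychotherapy_active", "psychotherapy_control")

#' Impute a missing change-score standard deviation
#'
#' Trials frequently omit the dispersion of the pre-post change. Following
#' the standard meta-analytic recovery chain, the change SD is reconstructed
#' from whichever statistic is available, in this priority order:
#'
#' 1. a reported change SD is used as-is;
#' 2. from a standard error: `sd = se * sqrt(n)`;
#' 3. from a 95% confidence interval: `sd = ((ci_high - ci_low) / 3.92) * sqrt(n)`;
#' 4. from a t statistic: `se = |change_mean| / |t|`, then rule 2;
#' 5. from a two-sided p value: `|t| = qt(1 - p/2, n - 1)`, then rule 4;
#' 6. from baseline and post SDs given a pre-post correlation `r`:
#'    `sd_change = sqrt(sd_pre^2 + sd_post^2 - 2 r sd_pre sd_post)`.
#'
#' Every rule that fires is recorded in `flags`, so downstream results carry
#' full imputation provenance.
#'
#' @param arm A single arm record (one-row data frame or list with the arm
#'   schema fields).
#' @param r Pre-post correlation used by rule 6, in (0, 1).
#' @return A list with `change_sd` (scale units) and `flags` (character
#'   vector drawn from `sd_from_se`, `sd_from_ci`, `sd_from_t`, `sd_from_p`,
#'   `change_sd_from_r`).
#' @export
impute_dispersion <- function(arm, r) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, r < 1)
  g <- function(field) {
    x <- arm[[field]]
    if (is.null(x) || length(x) == 0L || is.na(x[[1L]])) NA_real_ else as.numeric(x[[1L]])
  }
  n <- g("n")
  change_mean <- g("change_mean")
  if (is.na(change_mean) && !is.na(g("post_mean")) && !is.na(g("baseline_mean"))) {
    change_mean <- g("post_mean") - g("baseline_mean")
  }

  if (!is.na(g("change_sd"))) {
    return(list(change_sd = g("change_sd"), flags = character(0)))
  }
  if (!is.na(g("se_reported"))) {
    return(list(change_sd = g("se_reported") * sqrt(n), flags = "sd_from_se"))
  }
  if (!is.na(g("ci_low")) && !is.na(g("ci_high"))) {
    return(list(change_sd = ((g("ci_high") - g("ci_low")) / 3.92) * sqrt(n),
                flags = "sd_from_ci"))
  }
  if (!is.na(g("t_reported"))) {
    tt <- g("t_reported")
    if (tt == 0 && !is.na(change_mean) && change_mean != 0) {
      stop("arm ", arm[["arm_id"]],
           ": t_reported = 0 with nonzero change is degenerate", call. = FALSE)
    }
    se <- abs(change_mean) / abs(tt)
    return(list(change_sd = se * sqrt(n), flags = c("sd_from_t")))
  }
  if (!is.na(g("p_reported"))) {
    p <- g("p_reported")
    stopifnot(p > 0, p < 1)
    tt <- stats::qt(p / 2, df = n - 1, lower.tail = FALSE)
    if (!is.finite(tt)) {
      stop("arm ", arm[["arm_id"]], ": p_reported too small to invert",
           call. = FALSE)
    }
    se <- abs(change_mean) / tt
    return(list(change_sd = se * sqrt(n), flags = c("sd_from_p", "sd_from_t")))
  }
  sd_pre <- g("baseline_sd"); sd_post <- g("post_sd")
  if (!is.na(sd_pre) && !is.na(sd_post)) {
    return(list(
      change_sd = sqrt(sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post),
      flags = "change_sd_from_r"))
  }
  stop("arm ", arm[["arm_id"]], " of study ", arm[["study_id"]],
       ": no statistic available to impute the change SD", call. = FALSE)
}

hedges_j <- function(n) 1 - 3 / (4 * (n - 1) - 1)

#' Within-arm pre-post standardised mean difference
#'
#' Computes the standardised change from baseline for one trial arm. The
#' default estimator standardises by the baseline SD:
#' `d = (post_mean - baseline_mean) / baseline_sd` (negative values mean
#' symptom improvement). Its point value does not depend on the pre-post
#' correlation `r`; only the sampling variance does,
#' `var(d) = 2 (1 - r) / n + d^2 / (2 n)`, which is why the unknown `r` can be
#' handled afterwards by simulation. With `hedges = TRUE` (the default) the
#' estimate is multiplied by the small-sample factor
#' `J = 1 - 3 / (4 (n - 1) - 1)` and the variance by `J^2`.
#'
#' The alternative `standardizer = "change"` divides the mean change by the
#' (possibly imputed) change SD, with `var(d) = 1/n + d^2/(2n)`; its point
#' value generally depends on `r` through the imputation, and it is provided
#' for sensitivity analyses only.
#'
#' @inheritParams impute_dispersion
#' @param hedges Apply the Hedges small-sample correction (default `TRUE`).
#' @param standardizer `"baseline"` (default) or `"change"`.
#' @param arm_type Optional arm-type label (`"medication_control"` etc.);
#'   carried through if supplied.
#' @return A list of class `"arm_effect"`: `study_id`, `arm_id`, `arm_type`,
#'   `n`, `smd`, `variance`, `r_used`, `imputation_flags`.
#' @export
prepost_smd <- function(arm, r, hedges = TRUE,
                        standardizer = c("baseline", "change"),
                        arm_type = NA_character_) {
  standardizer <- match.arg(standardizer)
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, r < 1)
  g <- function(field) {
    x <- arm[[field]]
    if (is.null(x) || length(x) == 0L || is.na(x[[1L]])) NA_real_ else as.numeric(x[[1L]])
  }
  n <- g("n")
  if (is.na(n) || n < 2) stop("arm ", arm[["arm_id"]], ": n must be >= 2",
                              call. = FALSE)
  baseline_mean <- g("baseline_mean"); baseline_sd <- g("baseline_sd")
  change_mean <- g("change_mean")
  if (is.na(change_mean)) {
    if (is.na(g("post_mean")) || is.na(baseline_mean)) {
      stop("arm ", arm[["arm_id"]], ": neither change_mean nor post/baseline means",
           call. = FALSE)
    }
    change_mean <- g("post_mean") - baseline_mean
  }

  flags <- character(0)
  if (standardizer == "baseline") {
    if (is.na(baseline_sd) || baseline_sd <= 0) {
      stop("arm ", arm[["arm_id"]], ": baseline_sd must be present and > 0",
           call. = FALSE)
    }
    d <- change_mean / baseline_sd
    v <- 2 * (1 - r) / n + d^2 / (2 * n)
    # record provenance when the post SD itself had to be reconstructed
    if (is.na(g("post_sd")) && is.na(g("change_sd"))) {
      imp <- try(impute_dispersion(arm, r), silent = TRUE)
      if (!inherits(imp, "try-error")) flags <- imp$flags
    }
  } else {
    imp <- impute_dispersion(arm, r)
    if (imp$change_sd <= 0) stop("arm ", arm[["arm_id"]],
                                 ": non-positive change SD", call. = FALSE)
    d <- change_mean / imp$change_sd
    v <- 1 / n + d^2 / (2 * n)
    flags <- imp$flags
  }

  if (hedges) {
    j <- hedges_j(n)
    d <- j * d
    v <- j^2 * v
  }
  structure(list(study_id = as.character(arm[["study_id"]]),
                 arm_id = as.character(arm[["arm_id"]]),
                 arm_type = arm_type, n = n, smd = d, variance = v, r_used = r,
                 imputation_flags = flags),
            class = "arm_effect")
}

#' Compute pre-post SMDs for every arm of a database
#'
#' Applies [prepost_smd()] to each arm, labels it with its arm type
#' (modality crossed with role) and attaches the baseline severity as a
#' fraction of the arm's scale range, used later by the
#' regression-to-the-mean adjustment.
#'
#' @param db A `"trial_db"`.
#' @param r Pre-post correlation (single value applied to all arms, or a
#'   named vector giving one value per `study_id`).
#' @inheritParams prepost_smd
#' @return A data frame of class `"arm_effects"` with columns `study_id`,
#'   `arm_id`, `arm_type`, `role`, `control_type`, `n`, `smd`, `variance`,
#'   `r_used`, `imputation_flags` (comma-separated), `baseline_fraction`.
#' @export
compute_effects <- function(db, r = 0.675, hedges = TRUE,
                            standardizer = c("baseline", "change")) {
  stopifnot(inherits(db, "trial_db"))
  standardizer <- match.arg(standardizer)
  arms <- db$arms
  if (nrow(arms) == 0L) stop("database has no arms", call. = FALSE)
  modality <- db$studies$modality[match(arms$study_id, db$studies$study_id)]
  arm_type <- paste(modality, arms$role, sep = "_")

  if (length(r) == 1L && is.null(names(r))) {
    r_arm <- rep(as.numeric(r), nrow(arms))
  } else {
    r_arm <- as.numeric(r[arms$study_id])
    if (anyNA(r_arm)) stop("per-study r vector misses some study_ids", call. = FALSE)
  }

  sc <- db$scales[match(arms$scale, db$scales$name), , drop = FALSE]
  baseline_fraction <- (arms$baseline_mean - sc$min_score) /
    (sc$max_score - sc$min_score)

  if (standardizer == "baseline") {
    # fully vectorised: the point estimate is r-free and the variance closed form
    n <- arms$n
    if (any(is.na(n) | n < 2)) stop("arm ", arms$arm_id[is.na(n) | n < 2][1L],
                                    ": n must be >= 2", call. = FALSE)
    change <- ifelse(is.na(arms$change_mean),
                     arms$post_mean - arms$baseline_mean, arms$change_mean)
    if (anyNA(change)) stop("arm ", arms$arm_id[is.na(change)][1L],
                            ": neither change_mean nor post/baseline means",
                            call. = FALSE)
    bsd <- arms$baseline_sd
    if (any(is.na(bsd) | bsd <= 0)) {
      stop("arm ", arms$arm_id[is.na(bsd) | bsd <= 0][1L],
           ": baseline_sd must be present and > 0", call. = FALSE)
    }
    d <- change / bsd
    v <- 2 * (1 - r_arm) / n + d^2 / (2 * n)
    if (hedges) {
      jj <- hedges_j(n)
      d <- jj * d
      v <- jj^2 * v
    }
    no_disp <- is.na(arms$post_sd) & is.na(arms$change_sd)
    flags <- character(nrow(arms))
    flags[no_disp & !is.na(arms$se_reported)] <- "sd_from_se"
    flags[no_disp & is.na(arms$se_reported) &
            !is.na(arms$ci_low) & !is.na(arms$ci_high)] <- "sd_from_ci"
    flags[no_disp & is.na(arms$se_reported) &
            (is.na(arms$ci_low) | is.na(arms$ci_high)) &
            !is.na(arms$t_reported)] <- "sd_from_t"
    flags[no_disp & is.na(arms$se_reported) &
            (is.na(arms$ci_low) | is.na(arms$ci_high)) &
            is.na(arms$t_reported) & !is.na(arms$p_reported)] <- "sd_from_p,sd_from_t"
    res <- data.frame(
      study_id = arms$study_id, arm_id = arms$arm_id, arm_type = arm_type,
      role = arms$role, control_type = arms$control_type,
      n = n, smd = d, variance = v, r_used = r_arm,
      imputation_flags = flags, baseline_fraction = baseline_fraction,
      stringsAsFactors = FALSE)
  } else {
    out <- vector("list", nrow(arms))
    for (i in seq_len(nrow(arms))) {
      e <- prepost_smd(arms[i, ], r = r_arm[i], hedges = hedges,
                       standardizer = standardizer, arm_type = arm_type[i])
      out[[i]] <- data.frame(
        study_id = e$study_id, arm_id = e$arm_id, arm_type = e$arm_type,
        role = arms$role[i], control_type = arms$control_type[i],
        n = e$n, smd = e$smd, variance = e$variance, r_used = e$r_used,
        imputation_flags = paste(e$imputation_flags, collapse = ","),
        baseline_fraction = baseline_fraction[i],
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
  }
  res$arm_type <- factor(res$arm_type, levels = ARM_TYPES)
  class(res) <- c("arm_effects", "data.frame")
  res
}
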