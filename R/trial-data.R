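ARM_COLUMNS <- c("study_id", "arm_id", "role", "control_type", "n", "scale",
                 "baseline_mean", "baseline_sd", "post_mean", "post_sd",
                 "change_mean", "change_sd", "ci_low", "ci_high",
                 "se_reported", "t_reported", "p_reported",
                 "n_sessions", "session_minutes", "sessions_per_week",
                 "total_weeks", "total_hours")

STUDY_COLUMNS <- c("study_id", "modality", "n_sites", "subclinical",
                   "percent_female", "mean_age", "sd_age", "n_total")

SCALE_COLUMNS <- c("name", "min_score", "max_score")

MODALITIES <- c("medication", "psychotherapy")
ARM_ROLES <- c("active", "control")
CONTROL_TYPES <- c("pill_placebo", "waitlist", "tau", "other", "none")

#' Construct and validate a trial database
#'
#' Bundles study-level records, arm-level summary statistics and the scale
#' registry into one validated container. All referential and domain
#' invariants are checked here so that downstream analyses can assume a clean
#' database: known modality/role/control-type values, unique
#' `(study_id, arm_id)` pairs, every arm resolving to a study and to a
#' registered scale, positive baseline SDs, `control_type == "none"` exactly
#' for active arms, pill placebo only in medication studies, and at least one
#' of `post_mean` / `change_mean` per arm.
#'
#' @param studies Data frame with columns `study_id, modality, n_sites,
#'   subclinical, percent_female, mean_age, sd_age, n_total`.
#' @param arms Data frame with the arm schema (see [load_trials()]).
#' @param scales Data frame with columns `name, min_score, max_score`;
#'   defaults to [default_scales()].
#' @return An object of class `"trial_db"`: a list with elements `studies`,
#'   `arms`, `scales` and a `report` of counts and missingness tallies.
#' @export
trial_database <- function(studies, arms, scales = default_scales()) {
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  scales <- as.data.frame(scales, stringsAsFactors = FALSE)

  miss <- setdiff(STUDY_COLUMNS, names(studies))
  if (length(miss)) stop("studies table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(arms) > 0 || ncol(arms) > 0) {
    miss <- setdiff(ARM_COLUMNS, names(arms))
    if (length(miss)) stop("arms table missing columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  } else {
    arms <- empty_arm_table()
  }
  miss <- setdiff(SCALE_COLUMNS, names(scales))
  if (length(miss)) stop("scales table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  if (anyDuplicated(studies$study_id)) {
    stop("duplicate study_id: ",
         paste(unique(studies$study_id[duplicated(studies$study_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !studies$modality %in% MODALITIES
  if (any(bad)) stop("unknown modality '", studies$modality[bad][1L],
                     "' for study ", studies$study_id[bad][1L], call. = FALSE)
  with_sites <- !is.na(studies$n_sites)
  if (any(studies$n_sites[with_sites] < 1)) {
    stop("n_sites must be >= 1 when present", call. = FALSE)
  }
  pf <- studies$percent_female
  if (any(!is.na(pf) & (pf < 0 | pf > 100))) {
    stop("percent_female outside [0, 100]", call. = FALSE)
  }
  if (any(is.na(studies$n_total) | studies$n_total < 1)) {
    stop("n_total must be a positive integer for every study", call. = FALSE)
  }
  studies$subclinical <- as.logical(studies$subclinical)
  studies$subclinical[is.na(studies$subclinical)] <- FALSE

  if (anyDuplicated(scales$name)) stop("duplicate scale name in registry", call. = FALSE)
  for (i in seq_len(nrow(scales))) {
    scale_spec(scales$name[i], scales$min_score[i], scales$max_score[i]) # validates
  }

  if (nrow(arms) > 0) {
    key <- paste(arms$study_id, arms$arm_id, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("duplicate (study_id, arm_id): ", gsub("\r", " / ", dup), call. = FALSE)
    }
    bad <- !arms$role %in% ARM_ROLES
    if (any(bad)) stop("unknown role '", arms$role[bad][1L], "' in row ",
                       which(bad)[1L], " of arms table", call. = FALSE)
    bad <- !arms$control_type %in% CONTROL_TYPES
    if (any(bad)) stop("unknown control_type '", arms$control_type[bad][1L],
                       "' in row ", which(bad)[1L], " of arms table", call. = FALSE)
    orphan <- !arms$study_id %in% studies$study_id
    if (any(orphan)) stop("arm references unknown study_id '",
                          arms$study_id[orphan][1L], "'", call. = FALSE)
    unreg <- !arms$scale %in% scales$name
    if (any(unreg)) stop("arm references unregistered scale '",
                         arms$scale[unreg][1L], "'", call. = FALSE)
    bad <- (arms$role == "active") != (arms$control_type == "none")
    if (any(bad)) stop("control_type must be 'none' iff role is 'active' (arm ",
                       arms$arm_id[bad][1L], " of study ", arms$study_id[bad][1L],
                       ")", call. = FALSE)
    modality <- studies$modality[match(arms$study_id, studies$study_id)]
    bad <- arms$control_type == "pill_placebo" & modality != "medication"
    if (any(bad)) stop("pill_placebo control in non-medication study ",
                       arms$study_id[bad][1L], call. = FALSE)
    if (any(is.na(arms$n) | arms$n < 1)) stop("arm n must be a positive integer",
                                              call. = FALSE)
    bsd <- arms$baseline_sd
    if (any(!is.na(bsd) & bsd <= 0)) stop("baseline_sd must be > 0 when present",
                                          call. = FALSE)
    no_effect <- is.na(arms$post_mean) & is.na(arms$change_mean)
    if (any(no_effect)) {
      stop("arm ", arms$arm_id[no_effect][1L], " of study ",
           arms$study_id[no_effect][1L],
           " has neither post_mean nor change_mean", call. = FALSE)
    }
  }

  single <- setdiff(
    studies$study_id,
    names(which(table(arms$study_id) >= 2))
  )
  if (length(single) && nrow(arms) > 0) {
    warning("studies with fewer than 2 arms treated as partial (single-arm) ",
            "extractions: ", paste(single, collapse = ", "), call. = FALSE)
  }
  if (nrow(studies) == 0L) {
    warning("empty trial database (0 studies)", call. = FALSE)
  }

  modality <- studies$modality[match(arms$study_id, studies$study_id)]
  report <- list(
    n_studies = nrow(studies),
    n_arms = nrow(arms),
    studies_by_modality = table(factor(studies$modality, levels = MODALITIES)),
    arms_by_type = table(factor(
      paste(modality, arms$role, sep = "_"),
      levels = c("medication_active", "medication_control",
                 "psychotherapy_active", "psychotherapy_control"))),
    partial_studies = single,
    missing = c(
      post_sd = sum(is.na(arms$post_sd)),
      post_mean = sum(is.na(arms$post_mean)),
      n_sites = sum(is.na(studies$n_sites)),
      percent_female = sum(is.na(studies$percent_female)),
      mean_age = sum(is.na(studies$mean_age))
    )
  )

  rownames(studies) <- NULL
  rownames(arms) <- NULL
  rownames(scales) <- NULL
  structure(list(studies = studies, arms = arms, scales = scales,
                 report = report),
            class = "trial_db")
}

empty_arm_table <- function() {
  out <- as.data.frame(
    setNames(rep(list(character(0)), length(ARM_COLUMNS)), ARM_COLUMNS),
    stringsAsFactors = FALSE)
  num <- setdiff(ARM_COLUMNS, c("study_id", "arm_id", "role", "control_type", "scale"))
  for (cl in num) out[[cl]] <- numeric(0)
  out
}

#' @export
print.trial_db <- function(x, ...) {
  r <- x$report
  cat(sprintf("<trial_db> %d studies, %d arms\n", r$n_studies, r$n_arms))
  if (r$n_studies > 0) {
    cat("  studies:", paste(sprintf("%s %d", names(r$studies_by_modality),
                                    r$studies_by_modality), collapse = ", "), "\n")
    cat("  arms:   ", paste(sprintf("%s %d", names(r$arms_by_type),
                                    r$arms_by_type), collapse = ", "), "\n")
    cat("  missing post_sd:", r$missing[["post_sd"]],
        "| n_sites:", r$missing[["n_sites"]], "\n")
  }
  invisible(x)
}

SCHEMA_CLASSES <- c(study_id = "character", arm_id = "character",
                    role = "character", control_type = "character",
                    scale = "character", name = "character",
                    modality = "character", subclinical = "logical")

read_schema_csv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  classes <- ifelse(columns %in% names(SCHEMA_CLASSES),
                    SCHEMA_CLASSES[columns], "numeric")
  names(classes) <- columns
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE, colClasses = classes)
  if (nrow(df) == 0L && ncol(df) == 0L) return(df)
  miss <- setdiff(columns, names(df))
  if (length(miss)) stop(basename(path), " missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df[columns]
}

#' Load a trial database from CSV files
#'
#' Reads the per-arm summary-statistics table, the study table and the scale
#' registry, then validates them with [trial_database()]. Missing values must
#' be empty cells; sentinel numbers are not recognised.
#'
#' @param arms_path Path to the arms CSV (columns `study_id, arm_id, role,
#'   control_type, n, scale, baseline_mean, baseline_sd, post_mean, post_sd,
#'   change_mean, change_sd, ci_low, ci_high, se_reported, t_reported,
#'   p_reported, n_sessions, session_minutes, sessions_per_week, total_weeks,
#'   total_hours`).
#' @param studies_path Path to the studies CSV (columns `study_id, modality,
#'   n_sites, subclinical, percent_female, mean_age, sd_age, n_total`).
#' @param scales_path Path to the scales CSV (columns `name, min_score,
#'   max_score`); if `NULL`, [default_scales()] is used.
#' @return A validated `"trial_db"`.
#' @export
load_trials <- function(arms_path, studies_path, scales_path = NULL) {
  arms <- read_schema_csv(arms_path, ARM_COLUMNS)
  studies <- read_schema_csv(studies_path, STUDY_COLUMNS)
  scales <- if (is.null(scales_path)) default_scales()
            else read_schema_csv(scales_path, SCALE_COLUMNS)
  trial_database(studies, arms, scales)
}

#' Write a trial database to CSV files
#'
#' Writes `arms.csv`, `studies.csv` and `scales.csv` into `dir` in the exact
#' schema that [load_trials()] reads, with missing values as empty cells, so
#' that `load_trials(save_trials(db))` round-trips value-exactly. If the
#' database carries generating-truth metadata (see [generate_database()]) it
#' is written alongside as `truth.json`.
#'
#' @param db A `"trial_db"`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
save_trials <- function(db, dir) {
  stopifnot(inherits(db, "trial_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("arms.csv", "studies.csv", "scales.csv"))
  utils::write.csv(db$arms[ARM_COLUMNS], paths[1L], row.names = FALSE, na = "")
  utils::write.csv(db$studies[STUDY_COLUMNS], paths[2L], row.names = FALSE,
                   na = "")
  utils::write.csv(db$scales[SCALE_COLUMNS], paths[3L], row.names = FALSE, na = "")
  truth <- attr(db, "truth")
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Specify filtering criteria for sensitivity analyses
#'
#' A `filter_spec` is a conjunction of the exclusion rules used by the
#' sensitivity analyses. All criteria default to "off"; unknown criteria are
#' rejected.
#'
#' @param exclude_waitlist Drop whole studies whose control arms are all
#'   waitlist; in multi-control studies with at least one non-waitlist
#'   control, only the waitlist arms are dropped and the study is kept.
#' @param exclude_subclinical Drop studies flagged as having recruited
#'   subclinical samples.
#' @param scale_in Character vector of scale names to keep (e.g. `"CDRS-R"`),
#'   or `NULL` for no restriction. Studies with no arm on a kept scale drop out.
#' @param max_effect_variance Keep only arms whose pre-post SMD sampling
#'   variance, evaluated at the reference correlation `r_reference`, is
#'   strictly below this value; `NULL` for no restriction.
#' @param require_post_sd Keep only arms reporting a post-treatment SD.
#' @param all_female_excluded Drop studies with `percent_female == 100`.
#' @param r_reference Correlation at which the variance filter is evaluated
#'   (default 0.675, the midpoint of the 0.45-0.9 uncertainty range, making
#'   the filter deterministic even though the variance depends on r).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(exclude_waitlist = FALSE,
                        exclude_subclinical = FALSE,
                        scale_in = NULL,
                        max_effect_variance = NULL,
                        require_post_sd = FALSE,
                        all_female_excluded = FALSE,
                        r_reference = 0.675) {
  extra <- names(match.call(expand.dots = FALSE))[-1L]
  known <- names(formals(filter_spec))
  if (length(setdiff(extra, known))) {
    stop("unknown filter criterion: ", paste(setdiff(extra, known), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.logical(exclude_waitlist), is.logical(exclude_subclinical),
            is.logical(require_post_sd), is.logical(all_female_excluded))
  if (!is.null(max_effect_variance)) {
    stopifnot(is.numeric(max_effect_variance), max_effect_variance > 0)
  }
  structure(list(exclude_waitlist = exclude_waitlist,
                 exclude_subclinical = exclude_subclinical,
                 scale_in = scale_in,
                 max_effect_variance = max_effect_variance,
                 require_post_sd = require_post_sd,
                 all_female_excluded = all_female_excluded,
                 r_reference = r_reference),
            class = "filter_spec")
}

#' Apply sensitivity-analysis filters to a trial database
#'
#' Returns a new, re-validated database containing only the studies and arms
#' that satisfy every criterion in `criteria`; the input database is never
#' modified. Filters are idempotent and commute with one another.
#'
#' @param db A `"trial_db"`.
#' @param criteria A [filter_spec()].
#' @return A filtered `"trial_db"`.
#' @export
apply_filter <- function(db, criteria) {
  stopifnot(inherits(db, "trial_db"))
  if (!inherits(criteria, "filter_spec")) {
    stop("'criteria' must be a filter_spec", call. = FALSE)
  }
  studies <- db$studies
  arms <- db$arms

  if (criteria$exclude_subclinical) {
    studies <- studies[!studies$subclinical, , drop = FALSE]
  }
  if (criteria$all_female_excluded) {
    pf <- studies$percent_female
    studies <- studies[is.na(pf) | pf < 100, , drop = FALSE]
  }
  arms <- arms[arms$study_id %in% studies$study_id, , drop = FALSE]

  if (criteria$exclude_waitlist) {
    ctrl <- arms[arms$role == "control", , drop = FALSE]
    all_wl <- vapply(split(ctrl$control_type, ctrl$study_id),
                     function(ct) all(ct == "waitlist"), logical(1))
    drop_studies <- names(all_wl)[all_wl]
    studies <- studies[!studies$study_id %in% drop_studies, , drop = FALSE]
    arms <- arms[!arms$study_id %in% drop_studies &
                   arms$control_type != "waitlist", , drop = FALSE]
  }
  if (!is.null(criteria$scale_in)) {
    arms <- arms[arms$scale %in% criteria$scale_in, , drop = FALSE]
  }
  if (criteria$require_post_sd) {
    arms <- arms[!is.na(arms$post_sd), , drop = FALSE]
  }
  if (!is.null(criteria$max_effect_variance) && nrow(arms) > 0) {
    v <- vapply(seq_len(nrow(arms)), function(i) {
      eff <- try(prepost_smd(arms[i, ], r = criteria$r_reference), silent = TRUE)
      if (inherits(eff, "try-error")) NA_real_ else eff$variance
    }, numeric(1))
    arms <- arms[!is.na(v) & v < criteria$max_effect_variance, , drop = FALSE]
  }

  studies <- studies[studies$study_id %in% arms$study_id, , drop = FALSE]
  suppressWarnings(trial_database(studies, arms, db$scales))
}
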