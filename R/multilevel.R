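# -2 * restricted log-likelihood machinery for the three-level model
#   y_ij = x_ij' beta + u_j + w_ij + e_ij,
#   u_j ~ N(0, s2_study), w_ij ~ N(0, s2_arm), e_ij ~ N(0, v_ij) known.
# One observation per arm, so the marginal covariance is
#   V = diag(v + s2_arm) + s2_study * (same-study block of ones).
ml_reml_pieces <- function(s2_study, s2_arm, y, v, X, study) {
  n <- length(y)
  V <- diag(v + s2_arm, n)
  for (idx in split(seq_len(n), study)) {
    V[idx, idx] <- V[idx, idx] + s2_study
  }
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  Xi <- backsolve(cV, X, transpose = TRUE)
  yi <- backsolve(cV, y, transpose = TRUE)
  XtVX <- crossprod(Xi)
  XtVy <- crossprod(Xi, yi)
  cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cXtVX)) return(NULL)
  beta <- backsolve(cXtVX, backsolve(cXtVX, XtVy, transpose = TRUE))
  quad <- drop(crossprod(yi)) - drop(crossprod(XtVy, beta))
  logdetV <- 2 * sum(log(diag(cV)))
  logdetX <- 2 * sum(log(diag(cXtVX)))
  p <- ncol(X)
  loglik <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + quad)
  list(loglik = loglik, beta = drop(beta), XtVX = XtVX)
}

#' Fit the three-level random-effects meta-regression
#'
#' Fits `y_ij = x_ij' beta + u_j + w_ij + e_ij` to arm-level effects, where
#' `u_j` is a study-level random intercept with variance `sigma2_study`,
#' `w_ij` an arm-within-study random intercept with variance `sigma2_arm`,
#' and `e_ij` has known sampling variance `v_ij`. The two variance components
#' are estimated by REML (log-parameterised, multi-start bounded
#' quasi-Newton); `beta` by generalised least squares at the optimum. The
#' default design is the four arm-type indicators with no intercept, so each
#' coefficient is that arm type's pooled SMD.
#'
#' @param effects An `"arm_effects"` data frame from [compute_effects()] (or
#'   any data frame with columns `smd`, `variance`, `study_id`, `arm_type`).
#' @param moderators Optional data frame (or named matrix) of additional
#'   regression columns, e.g. a centered baseline severity.
#' @param design Optional full design matrix overriding the arm-type
#'   indicators entirely (used e.g. to verify parameterisation invariance).
#' @param sigma2_study,sigma2_arm Fix a variance component at a given value
#'   (e.g. 0) instead of estimating it; `NULL` (default) estimates it.
#' @param n_starts Number of optimisation starts (default 3).
#' @param start Optional starting values `c(sigma2_study, sigma2_arm)` tried
#'   before the default starts (used to warm-start across simulations).
#' @return An object of class `"multilevel_fit"`: `coefficients`, `se`,
#'   `vcov`, `sigma2_study`, `sigma2_arm`, `loglik_reml`, `converged`,
#'   `k_arms`, `k_studies`.
#' @export
fit_multilevel <- function(effects, moderators = NULL, design = NULL,
                           sigma2_study = NULL, sigma2_arm = NULL,
                           n_starts = 3, start = NULL) {
  y <- as.numeric(effects$smd)
  v <- as.numeric(effects$variance)
  study <- as.character(effects$study_id)
  if (any(!is.finite(y)) || any(v <= 0)) {
    stop("effects must have finite smd and variance > 0", call. = FALSE)
  }

  if (is.null(design)) {
    at <- as.character(effects$arm_type)
    lev <- ARM_TYPES[ARM_TYPES %in% at]
    X <- vapply(lev, function(l) as.numeric(at == l), numeric(length(at)))
    colnames(X) <- lev
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  }
  if (!is.null(moderators)) {
    M <- as.matrix(as.data.frame(moderators))
    X <- cbind(X, M)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  free <- c(study = is.null(sigma2_study), arm = is.null(sigma2_arm))
  fixed <- c(study = if (free[["study"]]) NA_real_ else sigma2_study,
             arm = if (free[["arm"]]) NA_real_ else sigma2_arm)

  expand <- function(par) {
    s2 <- fixed
    s2[free] <- exp(par)
    s2
  }
  negobj <- function(par) {
    s2 <- expand(par)
    pieces <- ml_reml_pieces(s2[["study"]], s2[["arm"]], y, v, X, study)
    if (is.null(pieces) || !is.finite(pieces$loglik)) return(1e10)
    -pieces$loglik
  }

  if (!any(free)) {
    best <- list(par = numeric(0), objective = negobj(numeric(0)), convergence = 0)
  } else {
    tau0 <- max(stats::var(y) - stats::median(v), 1e-3)
    base_starts <- list(rep(log(tau0 / 2), sum(free)),
                        rep(log(tau0), sum(free)),
                        rep(log(1e-3), sum(free)))
    starts <- base_starts[seq_len(min(n_starts, length(base_starts)))]
    if (!is.null(start)) {
      starts <- c(list(log(pmax(start[c(1, 2)][free], 1e-10))), starts)
    }
    fits <- lapply(starts, function(s) {
      stats::nlminb(s, negobj, lower = rep(-30, sum(free)),
                    upper = rep(6, sum(free)),
                    control = list(rel.tol = 1e-10, abs.tol = 1e-12))
    })
    ok <- vapply(fits, function(f) is.finite(f$objective), logical(1))
    fits <- fits[ok]
    if (!length(fits)) stop("multilevel REML optimisation failed from every start",
                            call. = FALSE)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
    if (!any(vapply(fits, function(f) f$convergence == 0, logical(1)))) {
      stop("multilevel REML did not converge after ", length(fits), " starts",
           call. = FALSE)
    }
  }

  s2 <- expand(best$par)
  s2[free & s2 < 1e-10] <- 0
  pieces <- ml_reml_pieces(s2[["study"]], s2[["arm"]], y, v, X, study)
  if (is.null(pieces)) stop("multilevel model singular at the optimum", call. = FALSE)
  vc <- solve(pieces$XtVX)
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- pieces$beta
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, se = sqrt(diag(vc)), vcov = vc,
                 sigma2_study = unname(s2[["study"]]),
                 sigma2_arm = unname(s2[["arm"]]),
                 loglik_reml = pieces$loglik, converged = TRUE,
                 k_arms = length(y), k_studies = length(unique(study))),
            class = "multilevel_fit")
}

#' @export
print.multilevel_fit <- function(x, ...) {
  cat(sprintf("<multilevel_fit> %d arms in %d studies | sigma2_study %.4f, sigma2_arm %.4f, REML ll %.3f\n",
              x$k_arms, x$k_studies, x$sigma2_study, x$sigma2_arm, x$loglik_reml))
  z <- stats::qnorm(0.975)
  for (nm in names(x$coefficients)) {
    b <- x$coefficients[[nm]]; s <- x$se[[nm]]
    cat(sprintf("  %-24s %8.3f (SE %.3f) [%.3f, %.3f]\n",
                nm, b, s, b - z * s, b + z * s))
  }
  invisible(x)
}

#' Contrast two coefficients of a multilevel fit
#'
#' `difference = beta_a - beta_b`,
#' `se = sqrt(Var(beta_a) + Var(beta_b) - 2 Cov(beta_a, beta_b))`,
#' `z = difference / se`.
#'
#' @param fit A `"multilevel_fit"`.
#' @param a,b Coefficient names (typically arm types).
#' @return List with `difference`, `se`, `z`.
#' @export
arm_type_contrast <- function(fit, a, b) {
  stopifnot(inherits(fit, "multilevel_fit"))
  nm <- names(fit$coefficients)
  if (!a %in% nm || !b %in% nm) {
    stop("arm type(s) absent from fit: ",
         paste(setdiff(c(a, b), nm), collapse = ", "), call. = FALSE)
  }
  diff <- fit$coefficients[[a]] - fit$coefficients[[b]]
  se <- sqrt(fit$vcov[a, a] + fit$vcov[b, b] - 2 * fit$vcov[a, b])
  list(difference = unname(diff), se = unname(se),
       z = if (se == 0) 0 else unname(diff / se))
}

#' Refit the multilevel model with a regression-to-the-mean adjustment
#'
#' Arms sampling more severe patients at baseline have more room to regress
#' toward the population mean, which could masquerade as a larger within-arm
#' improvement. The adjustment adds each arm's baseline severity, expressed
#' as a fraction of its scale range and centered at the grand mean, as a
#' moderator; the arm-type coefficients then estimate pooled SMDs at average
#' baseline severity, and [arm_type_contrast()] on the result tests whether
#' the control-arm difference survives the adjustment.
#'
#' @inheritParams fit_multilevel
#' @param baselines Baseline severity fraction per arm; defaults to the
#'   `baseline_fraction` column of `effects`. Must be complete.
#' @return A `"multilevel_fit"` with an extra `baseline_centered` coefficient
#'   (or, if the baselines are constant, the unadjusted fit with a warning).
#' @export
rtm_adjusted_fit <- function(effects, baselines = NULL, ...) {
  if (is.null(baselines)) baselines <- effects$baseline_fraction
  if (is.null(baselines) || anyNA(baselines)) {
    bad <- if (is.null(baselines)) "all" else
      paste(effects$arm_id[is.na(baselines)], collapse = ", ")
    stop("baseline severity missing for arms: ", bad, call. = FALSE)
  }
  centered <- baselines - mean(baselines)
  if (stats::sd(centered) == 0) {
    warning("baseline severity is constant; moderator dropped, returning unadjusted fit",
            call. = FALSE)
    return(fit_multilevel(effects, ...))
  }
  fit_multilevel(effects,
                 moderators = data.frame(baseline_centered = centered), ...)
}
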