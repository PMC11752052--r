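# Restricted log-likelihood for the one-level random-effects model, up to an
# additive constant. Used by both the REML estimator and its grid-search
# oracle in the tests.
reml_loglik_re <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Random-effects meta-analysis by inverse-variance pooling
#'
#' Pools a set of estimates with known sampling variances under the additive
#' between-study heterogeneity model `y_i ~ N(theta, v_i + tau^2)`.
#' `tau^2` is estimated either by restricted maximum likelihood (`"REML"`,
#' the default: one-dimensional bounded optimisation of the restricted
#' likelihood) or by the DerSimonian-Laird moment estimator (`"DL"`:
#' `tau^2 = max(0, (Q - (k-1)) / C)` with `Q = sum w (y - y_FE)^2`,
#' `C = sum w - sum w^2 / sum w`, `w = 1/v`). The pooled estimate uses
#' weights `1 / (v_i + tau^2)`; the 95% CI uses the normal quantile.
#'
#' @param y Numeric vector of estimates (k >= 1).
#' @param v Numeric vector of their sampling variances, all > 0.
#' @param method `"REML"` (default) or `"DL"`.
#' @return An object of class `"meta_result"`: list with `k`, `pooled`, `se`,
#'   `ci_low`, `ci_high`, `tau2`, `q` (the fixed-effect Q statistic) and
#'   `method`.
#' @examples
#' pool_random_effects(c(0.1, 0.3, 0.5), rep(0.01, 3), method = "DL")
#' @export
pool_random_effects <- function(y, v, method = c("REML", "DL")) {
  method <- match.arg(method)
  y <- as.numeric(y); v <- as.numeric(v)
  if (length(y) == 0L) stop("no estimates to pool", call. = FALSE)
  if (length(v) != length(y)) stop("y and v differ in length", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0)) {
    stop("all estimates must be finite with variance > 0", call. = FALSE)
  }
  k <- length(y)

  w_fe <- 1 / v
  mu_fe <- sum(w_fe * y) / sum(w_fe)
  q <- sum(w_fe * (y - mu_fe)^2)

  if (k == 1L) {
    tau2 <- 0
  } else if (method == "DL") {
    cc <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
    tau2 <- max(0, (q - (k - 1)) / cc)
  } else {
    upper <- max(10 * stats::var(y), 100 * max(v), 1)
    opt <- stats::optimize(reml_loglik_re, interval = c(0, upper),
                           y = y, v = v, maximum = TRUE, tol = 1e-12)
    tau2 <- opt$maximum
    # optimize never evaluates the endpoints; take the boundary if it wins
    if (reml_loglik_re(0, y, v) >= opt$objective) tau2 <- 0
    if (tau2 < 1e-10) tau2 <- 0
  }

  w <- 1 / (v + tau2)
  pooled <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(0.975)
  structure(list(k = k, pooled = pooled, se = se,
                 ci_low = pooled - z * se, ci_high = pooled + z * se,
                 tau2 = tau2, q = q, method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result k=%d method=%s>\n  pooled %.4f (SE %.4f), 95%% CI [%.4f, %.4f], tau2 %.4f, Q %.3f\n",
              x$k, x$method, x$pooled, x$se, x$ci_low, x$ci_high, x$tau2, x$q))
  invisible(x)
}

#' Test for subgroup differences between pooled estimates
#'
#' The between-groups heterogeneity Q test: with subgroup estimates
#' `theta_g` and standard errors `se_g`, weights `w_g = 1/se_g^2` and weighted
#' grand mean `theta_bar`, `Q_between = sum w_g (theta_g - theta_bar)^2` is
#' referred to a chi-square distribution with G - 1 degrees of freedom.
#'
#' @param results Named list of [pool_random_effects()] results, one per
#'   subgroup (>= 2).
#' @return An object of class `"subgroup_comparison"`: list with `results`,
#'   `q_between`, `df`, `p`.
#' @export
subgroup_difference <- function(results) {
  if (length(results) < 2L) stop("need at least 2 subgroups", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "meta_result")))
  theta <- vapply(results, `[[`, numeric(1), "pooled")
  se <- vapply(results, `[[`, numeric(1), "se")
  if (any(se == 0)) stop("subgroup with zero standard error is degenerate",
                         call. = FALSE)
  w <- 1 / se^2
  theta_bar <- sum(w * theta) / sum(w)
  q_between <- sum(w * (theta - theta_bar)^2)
  df <- length(results) - 1L
  structure(list(results = results, q_between = q_between, df = df,
                 p = stats::pchisq(q_between, df = df, lower.tail = FALSE)),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("<subgroup_comparison> Q_between = %.3f, df = %d, p = %.4g\n",
              x$q_between, x$df, x$p))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-16s k=%3d  %.3f [%.3f, %.3f]\n",
                nm, r$k, r$pooled, r$ci_low, r$ci_high))
  }
  invisible(x)
}

#' Cohen's d from group summary statistics
#'
#' Standardised mean difference between two independent groups using the
#' pooled SD: `s_p = sqrt(((k1-1) sd1^2 + (k2-1) sd2^2) / (k1 + k2 - 2))`,
#' `d = (mean1 - mean2) / s_p`. The 95% CI uses the large-sample variance
#' `var(d) = (k1 + k2)/(k1 k2) + d^2 / (2 (k1 + k2))`.
#'
#' @param k1,k2 Group sizes (`k1 + k2 >= 3`).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations.
#' @return List with `d`, `ci_low`, `ci_high`.
#' @export
cohens_d_pooled <- function(k1, mean1, sd1, k2, mean2, sd2) {
  stopifnot(k1 + k2 >= 3)
  sp <- sqrt(((k1 - 1) * sd1^2 + (k2 - 1) * sd2^2) / (k1 + k2 - 2))
  if (sp == 0) stop("pooled SD is zero: effect size undefined", call. = FALSE)
  d <- (mean1 - mean2) / sp
  vd <- (k1 + k2) / (k1 * k2) + d^2 / (2 * (k1 + k2))
  z <- stats::qnorm(0.975)
  list(d = d, ci_low = d - z * sqrt(vd), ci_high = d + z * sqrt(vd))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test:
#' `t = (mean1 - mean2) / sqrt(sd1^2/k1 + sd2^2/k2)` with
#' Welch-Satterthwaite (generally non-integer) degrees of freedom and a
#' two-sided p value. Cohen's d with its CI (pooled-SD form, see
#' [cohens_d_pooled()]) is attached for reporting.
#'
#' @inheritParams cohens_d_pooled
#' @return An object of class `"two_sample_comparison"`: list with the group
#'   summaries, `t`, `df`, `p`, `d`, `d_ci_low`, `d_ci_high`.
#' @examples
#' welch_t(28, 35.96, 25.16, 45, 3.04, 3.13)  # number of trial sites
#' @export
welch_t <- function(k1, mean1, sd1, k2, mean2, sd2) {
  stopifnot(k1 >= 2, k2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero: t undefined", call. = FALSE)
  a <- sd1^2 / k1
  b <- sd2^2 / k2
  t <- (mean1 - mean2) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (k1 - 1) + b^2 / (k2 - 1))
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  d <- cohens_d_pooled(k1, mean1, sd1, k2, mean2, sd2)
  structure(list(k1 = k1, k2 = k2, mean1 = mean1, mean2 = mean2,
                 sd1 = sd1, sd2 = sd2, t = t, df = df, p = p,
                 d = d$d, d_ci_low = d$ci_low, d_ci_high = d$ci_high),
            class = "two_sample_comparison")
}

#' @export
print.two_sample_comparison <- function(x, ...) {
  cat(sprintf("<two_sample_comparison> t(%.2f) = %.3f, p = %.4g\n",
              x$df, x$t, x$p))
  cat(sprintf("  group 1: k=%d, %.2f (SD %.2f); group 2: k=%d, %.2f (SD %.2f)\n",
              x$k1, x$mean1, x$sd1, x$k2, x$mean2, x$sd2))
  cat(sprintf("  Cohen's d = %.2f [%.2f, %.2f]\n", x$d, x$d_ci_low, x$d_ci_high))
  invisible(x)
}
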