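# one arm row with sensible defaults, overridable field by field
make_arm <- function(study_id = "S001", arm_id = "a1", role = "active",
                     control_type = if (role == "active") "none" else "pill_placebo",
                     n = 100, scale = "CDRS-R",
                     baseline_mean = 60, baseline_sd = 10,
                     post_mean = 45, post_sd = 10,
                     change_mean = NA_real_, change_sd = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     se_reported = NA_real_, t_reported = NA_real_,
                     p_reported = NA_real_,
                     n_sessions = NA_real_, session_minutes = NA_real_,
                     sessions_per_week = NA_real_, total_weeks = NA_real_,
                     total_hours = NA_real_) {
  data.frame(study_id = study_id, arm_id = arm_id, role = role,
             control_type = control_type, n = n, scale = scale,
             baseline_mean = baseline_mean, baseline_sd = baseline_sd,
             post_mean = post_mean, post_sd = post_sd,
             change_mean = change_mean, change_sd = change_sd,
             ci_low = ci_low, ci_high = ci_high, se_reported = se_reported,
             t_reported = t_reported, p_reported = p_reported,
             n_sessions = n_sessions, session_minutes = session_minutes,
             sessions_per_week = sessions_per_week, total_weeks = total_weeks,
             total_hours = total_hours, stringsAsFactors = FALSE)
}

make_study <- function(study_id = "S001", modality = "medication",
                       n_sites = 5, subclinical = FALSE, percent_female = 55,
                       mean_age = 14, sd_age = 1.5, n_total = 200) {
  data.frame(study_id = study_id, modality = modality, n_sites = n_sites,
             subclinical = subclinical, percent_female = percent_female,
             mean_age = mean_age, sd_age = sd_age, n_total = n_total,
             stringsAsFactors = FALSE)
}

# ---- independent oracles (deliberately naive implementations) ----

# restricted log-likelihood of the one-level random-effects model, typed out
# directly from the model density; maximised on a lattice
oracle_reml_tau2 <- function(y, v, upper = 1, step = 1e-5) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# restricted log-likelihood of the three-level model via plain solve() and
# determinant(); no Cholesky shortcuts, no shared code with the package
oracle_ml_loglik <- function(s2_study, s2_arm, y, v, X, study) {
  n <- length(y)
  V <- diag(v + s2_arm, n)
  same <- outer(study, study, "==")
  V <- V + s2_study * same
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(B)$modulus +
                       t(r) %*% Vi %*% r))
}

oracle_ml_grid <- function(y, v, X, study, upper_study, upper_arm, step = 1e-3) {
  g1 <- seq(0, upper_study, by = step)
  g2 <- seq(0, upper_arm, by = step)
  best <- c(NA, NA); best_ll <- -Inf
  for (a in g1) {
    for (b in g2) {
      ll <- oracle_ml_loglik(a, b, y, v, X, study)
      if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
    }
  }
  list(sigma2_study = best[1], sigma2_arm = best[2], loglik = best_ll)
}
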