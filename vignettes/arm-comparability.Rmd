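---
title: "Comparing trial arms across treatment modalities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing trial arms across treatment modalities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armcompare)
```

## The problem

Guidelines for youth depression rest largely on indirect comparisons:
meta-analyses of psychotherapy trials on one side and of antidepressant
trials on the other. Such comparisons are only valid if the two bodies of
evidence are comparable — in who enrols (severity, sex, age) and in how the
trials are run (control conditions, number of sites, intensity matching).
`armcompare` implements the quantitative machinery for auditing that
comparability on a flat per-arm summary-statistics table: within-arm pre–post
standardised mean differences (SMDs) under uncertainty about the pre–post
correlation, a three-level meta-regression over the four arm types
(medication active/control, psychotherapy active/control), stability and
sensitivity analyses, baseline-comparability meta-analyses, and trial-design
comparisons.

## Data model

A `trial_db` bundles three validated tables: study records (modality, sites,
sex/age composition, total n), arm records (role, control type, n, baseline
and endpoint summaries on a named scale, optional change statistics and
session-intensity descriptors), and a scale registry with each instrument's
minimum and maximum total score. Missing values are empty CSV cells, never
sentinel numbers, and every downstream operation treats missingness
explicitly. Validation enforces referential integrity, the control-type
rules (`none` exactly for active arms; pill placebo only in medication
studies), positive baseline SDs, and at least one of `post_mean` /
`change_mean` per arm. Single-arm studies are accepted as partial
extractions with a warning rather than rejected, since multi-arm source
reviews occasionally contribute only one usable arm.

Severity is compared across instruments on the *fraction-of-range* metric:
`fraction = (score - min) / (max - min)`. On the CDRS-R (17–113, range 96) a
fraction of 0.36 corresponds to a total score of `17 + 0.36 * 96 = 51.56`
and 0.42 to 57.32. The transformation and its exact inverse are
`score_to_fraction()` / `fraction_to_score()`.

## The within-arm effect size

The effect of interest is the standardised change from baseline within one
arm, with negative values meaning improvement:

$$ d = \frac{\bar{y}_{\text{post}} - \bar{y}_{\text{pre}}}{s_{\text{pre}}},
\qquad
\widehat{\mathrm{Var}}(d) = \frac{2(1 - r)}{n} + \frac{d^2}{2n}, $$

where $r$ is the correlation between a participant's baseline and endpoint
scores. We standardise by the **baseline SD** rather than the change-score
SD. The choice matters: with the baseline standardiser the *point estimate*
is free of $r$ — only the standard error depends on it — which is exactly
the situation the correlation simulation (below) is designed for. A
change-SD standardiser ($d = \Delta / s_\Delta$, variance $1/n + d^2/2n$) is
available behind `standardizer = "change"` for sensitivity use; its point
value inherits the $r$-dependence of the imputed change SD. The Hedges
small-sample factor $J = 1 - 3/(4(n-1) - 1)$ is applied by default
(`hedges = TRUE`), multiplying the estimate by $J$ and the variance by
$J^2$.

When dispersion statistics are missing, `impute_dispersion()` reconstructs
the change SD through the standard recovery chain, in priority order:
reported change SD; SD from a standard error ($sd = se\sqrt{n}$); from a
95% CI ($sd = \sqrt{n}\,(\text{hi} - \text{lo})/3.92$); from a t statistic
($se = |\Delta|/|t|$); from a two-sided p value (invert the t distribution
with $n-1$ df, then the t rule); and finally from baseline and endpoint SDs
given $r$ ($s_\Delta^2 = s_1^2 + s_2^2 - 2 r s_1 s_2$). Every rule that
fires is recorded in `imputation_flags`, so each effect carries its
provenance. A p value of exactly 0 (or one too small for the t inversion)
is refused rather than silently truncated.

## Handling the unknown pre–post correlation

$r$ is almost never reported. Rather than fixing a guess, the analysis is
repeated over `n_sims` simulated datasets (1000 by default; the test suites
use 200) whose correlations are drawn uniformly from `[0.45, 0.9]`. The
default draws one shared $r$ per dataset (`per_dataset`); an independent
draw per study (`per_study`) is available, since the evidence for either
convention is thin. Uniformity over the stated range is our choice — the
range's midpoint 0.675 is also used as the fixed reference correlation
wherever a single deterministic value is needed (the variance-based
sensitivity filter, the single-fit regression-to-the-mean section).

Results are aggregated as **means across simulations** of both the
coefficients and their CI bounds, with the between-simulation SD reported
alongside; Rubin-style pooling was considered and rejected as the default
because the aggregation target here is the published convention of averaging
across simulated datasets. The stability analysis records, per dataset, the
directional $z$ of the control-arm contrast (positive when the medication
control improves more than the psychotherapy control) and reports the
running and final proportion exceeding 1.645 (one-sided $\alpha = 0.05$).

## The three-level model

Arms are nested in studies, and multi-arm studies contribute correlated
evidence. `fit_multilevel()` fits

$$ y_{ij} = x_{ij}^\top \beta + u_j + w_{ij} + \varepsilon_{ij}, \qquad
u_j \sim N(0, \sigma^2_{\text{study}}),\;
w_{ij} \sim N(0, \sigma^2_{\text{arm}}),\;
\varepsilon_{ij} \sim N(0, v_{ij}), $$

with the sampling variances $v_{ij}$ known. The default design is the four
arm-type indicators with no intercept, so each coefficient is that arm
type's pooled SMD. The two variance components are estimated by REML on the
log scale with three-start bounded quasi-Newton optimisation (`nlminb`,
objective tolerance 1e-10); $\beta$ is generalised least squares at the
optimum. Sampling covariance between arms of the same study is set to zero
— within-group SMDs come from disjoint participant groups — and shared
study-level influences are absorbed by $u_j$. Estimated components below
1e-10 are reported as exactly zero. Non-convergence from every start raises
an error; it is never reported silently. Within the simulation loop each
fit warm-starts from the previous optimum, which is a pure speed-up: the
added start can only improve the objective.

Numerical cross-checks enforced by the test suite: the REML solution matches
a brute-force lattice search of the restricted likelihood (resolution 1e-3)
on a six-study fixture, and matches `metafor::rma.mv` (used strictly as an
independent oracle) on the full synthetic database; the objective is
invariant to reparameterisation of the design; with one arm per study and
$\sigma^2_{\text{arm}} = 0$ the model collapses to the one-level
random-effects pool.

### Regression to the mean

More severe samples have more room to regress toward the population mean,
which could mimic a larger within-arm improvement. `rtm_adjusted_fit()`
adds each arm's baseline severity fraction, centered at the grand mean, as
a linear moderator and refits. The published adjustment this mirrors is
specified at the individual level; in this aggregate-data setting we adapt
it as an arm-level, fraction-scale, centered linear moderator — recorded
here as an assumption. A constant moderator is dropped with a warning. On a
fixture generated with an explicit baseline slope of −2 per fraction unit,
the recovered slope's CI covers the truth, and a permuted moderator covers
zero at the nominal rate.

## One-level meta-analysis and the design comparisons

`pool_random_effects()` implements inverse-variance pooling with either the
REML or DerSimonian–Laird $\tau^2$ (REML is the default, matching
contemporary practice; the two agree exactly whenever the DL truncation
binds). CIs use the normal quantile 1.96 throughout; no Knapp–Hartung
adjustment is applied, consistent with the interval widths the pipeline is
meant to reproduce. `subgroup_difference()` is the between-groups Q test
with weights $1/se_g^2$ on $G-1$ df.

Baseline comparability (`compare_baseline_characteristics()`) pools, per
modality and per variant (overall / excluding subclinical / excluding
waitlist): severity fractions with $se = sd/\sqrt{n}$ (the study's
arm-size-weighted baseline SD over the scale range), percent female with
binomial variance $100^2\,p(1-p)/n$, and age with $se = sd_{\text{age}}/\sqrt{n}$.
Studies contribute one row each (multi-arm studies are collapsed by
arm-size weighting) — the alternative, one row per arm, would double-count
participants' baseline information. All-female samples are excluded from
the sex analysis; they also carry zero binomial variance, so the exclusion
is doubly forced. Cells with fewer than two usable studies are reported
unavailable rather than raising an error.

Trial-design comparisons use the Welch t-test everywhere (the published
non-integer dfs identify Welch) and pooled-SD Cohen's d with large-sample
CI. The intensity battery over `{n_sessions, sessions_per_week,
session_minutes, total_hours}` is available-case per variable and evaluated
at the Bonferroni threshold $0.05/4 = 0.0125$. Multisite means
`n_sites > 1`.

## Sensitivity filters

`filter_spec()` expresses each published sensitivity analysis as a
composable criterion: waitlist exclusion (removing whole studies whose
controls are all waitlist; multi-control studies keep their non-waitlist
controls), subclinical exclusion (a study-level input flag, not inferred
from severity), instrument restriction (CDRS-R or HAM-D), a post-SD
reporting requirement, and a variance ceiling. "Variance below 0.02" is
read as a strict inequality on the SMD sampling variance evaluated at the
reference correlation 0.675 — the variance depends on $r$, so a fixed
reference makes the filter deterministic; no tie rule is needed because the
inequality is strict. Filters are idempotent and commute, which the test
suite checks property-style.

## The synthetic evidence base

Because the underlying trial-level dataset lives in an external repository
without a stated accession, the package ships a generator
(`generate_database()`) whose defaults emulate the published evidence base:
53 psychotherapy and 39 medication studies; true control-arm change SMDs of
−0.6 (psychotherapy) and −1.9 (pill placebo); active-arm truths of −1.3 and
−2.3, which are **not** published and are configurable assumptions chosen
to preserve plausible active-over-control margins; between-study SD 0.3 and
between-arm SD 0.1 on the SMD scale; severity fractions 0.37/0.42; percent
female 61.36/53.72 with two all-female psychotherapy trials; ages
14.3/13.69; site counts centred at 3/36; a 14:28:20 waitlist:TAU:other
control mix; and intensity distributions centred at the published
active/control group summaries. Sample moments follow their exact laws
under normality: means are bivariate normal with correlation $r \sim
U(0.45, 0.9)$ per study, SDs follow the scaled chi-square with $n-1$ df.
Per-arm sample sizes (log-normal, medians 40 psychotherapy / 90 medication,
clamped to [10, 400]) and the missingness rates are conventions recorded in
`truth.json` alongside every generated database.

What the generator does *not* emulate: publication bias, non-normal
outcomes, rounding conventions of source papers beyond 4 decimals,
correlated sampling of pre and post SDs, cluster randomisation, and
selective reporting correlated with effect size. Clamping the intensity
draws at their natural floors also shifts some control-arm means above
their nominal targets. Passing the recovery tests therefore shows the
pipeline is consistent and correctly propagates the stated uncertainty — it
cannot certify behaviour under data pathologies the generator omits.

## Problem sizes and runtime conventions

The test suites run the correlation simulation at 200 datasets (the
convention for desk-scale runs; full analyses default to 1000), the null
calibrations at 400 seeds (subgroup test) and 1000 seeds (intensity
battery), the permutation null at 200 permutations on a 24-study database,
and the REML lattice oracles at resolutions 1e-5 (one-dimensional) and 1e-3
(two-dimensional). These sizes were chosen so each check has enough
replications for its stated tolerance (e.g. ±2 percentage points around a
5% rejection rate) while remaining a routine desk run.

## Known limitations

* The choice of each study's primary scale follows an out-of-band hierarchy
  and is taken as an input column; the package does not re-derive it.
* The exact published SMD estimator is not stated; the baseline-SD form is
  our reasoned default and the change-SD form is provided for sensitivity.
* Exact p values printed alongside heavily rounded summary tables cannot
  always be recovered to the last digit; recomputed statistics are asserted
  at the printed precision, allowing the source's own rounding.
* CIs use normal quantiles everywhere; t-type intervals for the multilevel
  coefficients would widen them slightly at small K.
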