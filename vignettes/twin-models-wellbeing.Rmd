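---
title: "Twin models of child wellbeing across environmental disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models of child wellbeing across environmental disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinwell)
```

## The scientific setting

A large, abrupt change to the shared environment — a pandemic lockdown that
confines both children of a twin pair to the same home — is a natural
experiment for behavior genetics. Parent-rated child wellbeing on the 0–10
Cantril ladder, measured before, during and after such a disruption, lets us
ask three questions that this package operationalizes end to end:

1. **Mean trends.** How did average wellbeing move across survey waves, and
   how do sex, age and parental educational attainment (PEA) shape it?
2. **Genetic architecture over time.** How did the additive-genetic (A),
   shared-environment (C) and non-shared environment (E) variance components
   change across periods, and how much does each component contribute to the
   *stability* of wellbeing between periods?
3. **Rater agreement and rater bias.** When both parents rate both twins,
   how much of a parent's rating reflects the child phenotype both parents
   see, and how much is rater-specific — in particular the systematic,
   twin-shared rating tendency (rater bias) that masquerades as shared
   environment in single-rater analyses?

Because the underlying cohort data are not redistributable, the package
pairs every estimator with a seeded synthetic-cohort generator whose
defaults encode the reported study conditions, so the whole analysis chain
is exercised and tested without any external data.

## The classical twin decomposition

MZ twins share essentially all segregating genes, DZ twins half on average.
For a single trait the implied twin-pair covariance matrix is

$$\mathrm{Var}(y) = a^2 + c^2 + e^2,\qquad
\mathrm{Cov}(y_1,y_2) = k_A\,a^2 + c^2,\quad k_A = 1\ (\mathrm{MZ}),\ 0.5\ (\mathrm{DZ}).$$

`expected_cov_univariate()` builds these matrices (including the ADE
variant with $k_D = 1$ or $0.25$), and `choose_ace_or_ade()` implements the
conventional rule: ACE if $r_{MZ} < 2 r_{DZ}$, ADE if $r_{MZ} > 2 r_{DZ}$.
Exact ties resolve to ACE — C and D are not jointly identifiable in the
classical design, and ACE is the operative family for wellbeing, where MZ
correlations sit well below twice the DZ correlations.

## Correlated factors model across four periods

Waves collapse into four periods (pre, early, late, post; the default map
is wave 0 → pre, 1–2 → early, 3–4 → late, 5+ → post, configurable in
`wave_to_period()`). Each component becomes a $4\times4$ PSD matrix over
periods: $\Sigma_A$, $\Sigma_C$, $\Sigma_E$. The expected covariance of a
twin pair's $8$-vector is

$$\begin{pmatrix} P & k_A\,\Sigma_A + \Sigma_C \\
k_A\,\Sigma_A + \Sigma_C & P \end{pmatrix},
\qquad P = \Sigma_A + \Sigma_C + \Sigma_E .$$

Derived quantities follow directly: component correlations
$r_X[i,j] = \Sigma_X[i,j]/\sqrt{\Sigma_X[i,i]\Sigma_X[j,j]}$ (a genetic
correlation below 1 indicates partially different genes at work across
environments), and standardized shares $\Sigma_X[i,j]/P[i,j]$, which sum to
1 per cell by construction.

```{r derived}
params <- cf_params_wellbeing() # default generating values
round(component_correlations(params)$rA, 2)
round(diag(standardize_components(params)$C), 2)
```

Two standardization choices were genuinely open:

* **Phenotypic denominator.** We standardize against the *model-implied*
  phenotypic matrix $P = \Sigma_A+\Sigma_C+\Sigma_E$, not a separately
  fitted saturated variance. Published tables of this kind sometimes round
  the phenotypic entry independently of the component sum (e.g. a printed
  1.06 against components summing to 1.07); using the component sum keeps
  every reported share triplet summing to exactly 1.
* **Derived-quantity intervals.** Profile likelihood is the primary
  interval method for single variance components (`profile_ci()`); for
  derived entries of the matrix-valued model the reported tables carry
  point estimates, with a seeded nonparametric bootstrap as the documented
  interval route, because a single matrix entry is not a single parameter
  of the matrix-root parameterization that guarantees positive
  semi-definiteness.

## Raw-data (full-information) likelihood and optimization

All twin fits maximize the raw-data multivariate-normal likelihood: each
family contributes the log-density of exactly its observed subvector
(`fiml_loglik()`), so partial wave overlap and single-responder families
are used rather than discarded, and with complete data the objective equals
the dense likelihood to numerical precision. Internally, families are
grouped by missing-data pattern and zygosity so each pattern's covariance
submatrix is factored once per evaluation.

Numerical choices, in one place:

* **PSD parameterization.** Component matrices are parameterized as
  $\Sigma = LL'$ with unconstrained lower-triangular $L$; scalar components
  as squared standard deviations. Variance estimates are therefore bounded
  at zero without active box constraints, which matches reported intervals
  that touch 0 and removes optimizer boundary pathologies.
* **Starting values.** Falconer-style moment estimates from the sample
  cross-twin covariances ($\hat\Sigma_A = 2(S_{MZ}-S_{DZ})$,
  $\hat\Sigma_C = 2S_{DZ}-S_{MZ}$, remainder to E), projected to PSD by an
  eigenvalue floor.
* **Restarts.** Quasi-Newton search (`nlminb`, relative tolerance
  $10^{-12}$) with jittered restarts: 5 for the univariate and psychometric
  fits, 3 (moment-anchored) for the 36-parameter correlated-factors fit,
  where each start costs tens of seconds at study scale and the
  moment-based start is already in the attraction basin; the count is an
  argument on every fitter.
* **Indefinite proposals.** A non-PD observed submatrix makes the
  log-likelihood $-\infty$; the optimizer wrapper maps it to a large finite
  barrier.
* **Degenerate inputs.** Zero-variance data, periods with no complete
  cross-twin pairs (A/C split unidentified) and single-rater datasets in
  the multi-rater fit are detected and reported rather than silently fit.
* **Profile intervals.** The 95% interval is the set of values where the
  profiled $-2\ln L$ rises at most 3.841; bracketing expands geometrically
  from a curvature-based step, respects the zero boundary, and falls back
  to a seeded bootstrap with a warning when it cannot bracket.

## Psychometric multi-rater model

Mother and father ratings of both twins give a 4-variate observation
(m1, f1, m2, f2). Each rating is the sum of a *common* latent child
phenotype (rater agreement, ACE-decomposed) and a *rater-specific* part
(disagreement, also ACE-decomposed). Rater-specific C is fully shared
across twins within a rater — this is the rater-bias component, a
systematic over- or under-rating tendency. The implied covariance
structure (`build_multirater_expected_cov()`) makes the same-twin
cross-rater covariance equal to the common variance $A+C+E$, identical for
MZ and DZ groups; this is exactly the first identifying constraint tested
by `fit_constrained_saturated()` (the second equates cross-twin
cross-rater covariances across twin order; the comparison model releases
precisely those constraints, 3 df, tested at $\alpha = 0.05$).

One definitional point matters when comparing shares across reports. For
each rater, the *per-rater* common-view share is
$(A+C+E)/(A+C+E+A_r+C_r+E_r)$. The *combined* share divides the common
variance by the two-rater total $A+C+E+A_m+C_m+E_m+A_f+C_f+E_f$ (common
counted once). Only the combined reading is arithmetically consistent with
quoting a cross-rater correlation of 0.50 alongside a common-view share
near one third: with unit rater variances the cross-rater correlation
*equals* the per-rater common share, so a 0.50 correlation forces the
quoted ~35% to be the combined share. `decompose_views()` therefore emits
both, and the package's headline common-view figure is the combined one.

The generator's per-period scenario sets (`multirater_params_wellbeing()`)
were calibrated to the reported cross-rater correlations (0.50 / 0.35 /
0.40 / 0.43), twin correlations and share decompositions jointly, with
rater totals normalized to 1. The reported post-pandemic twin correlations
and specific shares are not exactly jointly representable under the model;
the post scenario prioritizes the cross-rater correlation and the share
decomposition. A consequence worth knowing: the reported pre-pandemic DZ
cross-twin cross-rater correlation (0.38) slightly exceeds the MZ value
(0.37), which no parameter set can reproduce (the difference is
$0.5\,A \ge 0$) — sampling noise of that size is expected and harmless.

The bias mechanism itself is testable: fitting a *single-rater* ACE model
to data generated with nonzero $C_m$ recovers approximately $C + C_m$ as
"shared environment" — the inflation that motivates the multi-rater design
— and the suite asserts this as a strict inequality at large $n$.

## Mean trends: random-intercept mixed model

Per cohort, wellbeing follows
$Y = (\beta_1 + b_i) + \beta_2\,\mathrm{wave} + \beta_3\,\mathrm{sex} +
\beta_4\,\mathrm{age} + \beta_5\,\mathrm{PEA} + \beta_6\,\mathrm{rater} + e$,
with wave categorical (baseline reference for the longitudinal twin cohort,
wave 2 for the cross-sectional cohorts), fit by maximum likelihood (not
REML). For twin cohorts the individual intercept is nested in a family
intercept; the marginal family covariance has the closed form
$\sigma^2_f + \sigma^2_i + \sigma^2_e$ on the diagonal,
$\sigma^2_f + \sigma^2_i$ within individuals and $\sigma^2_f$ across
twins. The implementation collapses the likelihood with two nested
Woodbury identities, so an evaluation is a handful of grouped sums and the
study-scale fit takes about a second; agreement with `nlme::lme` on the
same model is part of the test suite (fixed effects to $10^{-4}$,
log-likelihoods to $10^{-6}$).

Cross-sectional cohorts keep the specified individual intercept even
though, with one observation per child, only $\sigma^2_i + \sigma^2_e$ is
identified — the fit warns and flags this, and the fixed effects are
unaffected (OLS-equivalent). Degrees of freedom for t statistics use a
containment-style rule (within-individual terms against observation-level
df, others against group counts) and are informative only; exact
finite-sample df are not defined for this estimator. Estimated marginal
means per wave average the fixed-effect prediction over the observed
covariate distribution and are invariant to reference recoding. For
individuals with several pre-pandemic records, `select_baseline()` keeps
the latest one (ties: first record in table order, flagged).

## What the generator emulates — and what it does not

`simulate_twin_cohort()` draws latent A/C/E deviates with cross-twin
correlations (A: 1 MZ / 0.5 DZ; C: 1; E: 0) from the correlated-factors
matrices, adds per-period rater-specific deviates when a multi-rater
scenario is attached, and emits one row per child × period × responding
rater. Defaults encode the study conditions: component matrices at the
reported four-period estimates; baseline age uniform on 7–12 years with
period offsets; sex 50/50 (MZ pairs same-sex); PEA at the reported
low/middle/high proportions; per-period mean levels near the reported
marginal means with small age and sex effects. Missingness is
missing-completely-at-random (`missingness_spec()`), with the baseline
period dropped at the family level (both twins share baseline
availability) and a `pairwise_overlap` convenience targeting the ~40%
two-survey overlap of the study (per-period observation probability
$\sqrt{0.4}$). A single pre-pandemic occasion is simulated; the source
cohort pooled baseline measurements over many years, which the generator
does not attempt to reproduce.

Scores are continuous by default — every model here treats the ladder as
continuous, and continuous scores keep estimator tests exact.
`discretize_cantril()` (round half-up, clip to 0–10) is opt-in; at typical
means and variances it adds roughly the uniform rounding variance 1/12.
MCAR missingness, simulated "other"-rater absence (excluded from all
genetic models anyway), and the absence of selective participation mean
that passing recovery tests demonstrates estimator correctness under the
stated model, not robustness to informative dropout, floor effects of the
discrete ladder, or violations of the equal-environments assumption.

Mixed-model cohorts come from `simulate_lmm_cohort()` with design
templates: a longitudinal twin cohort (10,000 families by default, baseline
participation 0.85, pandemic-wave participation 0.40, mother rates ~90% of
rows) and cross-sectional singleton cohorts (each child in exactly one
wave). Variance components for the twin template
($\sigma^2_f = 0.35, \sigma^2_i = 0.25, \sigma^2_e = 0.45$; twin intraclass
correlation $\approx 0.57$) are plausible values for parent-rated
wellbeing; the source report does not publish its variance components.

## Problem sizes used by the checks

The recovery checks run at the study's scale: 2,500 pairs per zygosity for
the correlated-factors fit, 3,000 pairs per zygosity for the multi-rater
fits, ~20,000 twin children for the longitudinal mixed model and 2,500
singletons for the clinical-cohort model. Property suites (simulator vs
model-implied covariance, FIML vs dense likelihood, Falconer closed forms,
profile-interval coverage, constraint-test calibration) use smaller sizes
chosen so each statement is still decisive at three Monte-Carlo standard
errors.

## Known limitations

* Continuous-normal likelihood throughout: no ordinal/threshold liability
  models for the discretized ladder, no ADE longitudinal variant, no
  Cholesky/simplex alternatives to the correlated-factors parameterization.
* MCAR is the only missingness mechanism; FIML is unbiased under it (and
  under MAR given the modeled variables), but informative dropout is out of
  scope.
* Rater bias is modeled as fully shared across twins within a rater; bias
  that correlates imperfectly across twins is indistinguishable from
  rater-specific A/E here.
* Mixed-model t-statistic df are approximate by design.
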