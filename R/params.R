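# Parameter containers: univariate ACE/ADE components, four-period correlated
# factors components, psychometric multi-rater components, and the
# random-intercept mixed-model specification, together with default
# generating values calibrated to published estimates for parent-rated child
# wellbeing across four pandemic periods.

#' Univariate variance components (A, C, E and optional D)
#'
#' @param a2 additive-genetic variance.
#' @param c2 shared-environment variance.
#' @param e2 non-shared environment variance (includes measurement error;
#'   must be strictly positive).
#' @param d2 non-additive (dominance) genetic variance. In fitted models C
#'   and D are alternative families and may not both be nonzero.
#' @return An object of class `ace_params`.
#' @export
#' @examples
#' ace_params(0.38, 0.52, 0.17)
ace_params <- function(a2, c2 = 0, e2, d2 = 0) {
  stopifnot(a2 >= 0, c2 >= 0, d2 >= 0, e2 > 0)
  structure(list(a2 = a2, c2 = c2, e2 = e2, d2 = d2), class = "ace_params")
}

total_variance <- function(p) p$a2 + p$c2 + p$e2 + p$d2

#' @export
print.ace_params <- function(x, ...) {
  v <- total_variance(x)
  cat(sprintf("ACE components: a2=%.3f c2=%.3f e2=%.3f d2=%.3f (total %.3f)\n",
              x$a2, x$c2, x$e2, x$d2, v))
  invisible(x)
}

#' Four-period correlated-factors components
#'
#' The correlated factors model gives each period its own A, C and E factor;
#' the factors of one component correlate across periods, so each component is
#' a symmetric positive semi-definite matrix over periods. The phenotypic
#' covariance matrix is their elementwise sum. The mean model carries one
#' intercept per period plus linear age and sex (female) effects shared over
#' periods.
#'
#' @param sigma_a,sigma_c,sigma_e symmetric PSD matrices over periods.
#' @param periods period labels (row/column order of the matrices).
#' @param intercepts per-period means at age 0, male.
#' @param beta_age,beta_sex linear mean effects of age (years) and female sex.
#' @return Object of class `cf_params`.
#' @export
cf_params <- function(sigma_a, sigma_c, sigma_e,
                      periods = default_periods(),
                      intercepts = rep(0, length(periods)),
                      beta_age = 0, beta_sex = 0) {
  k <- length(periods)
  for (nm in c("sigma_a", "sigma_c", "sigma_e")) {
    m <- get(nm)
    if (!is.matrix(m) || any(dim(m) != k)) {
      stop(sprintf("'%s' must be a %dx%d matrix", nm, k, k))
    }
    check_psd(m, nm)
  }
  stopifnot(length(intercepts) == k)
  structure(list(sigma_a = `dimnames<-`(sigma_a, list(periods, periods)),
                 sigma_c = `dimnames<-`(sigma_c, list(periods, periods)),
                 sigma_e = `dimnames<-`(sigma_e, list(periods, periods)),
                 periods = periods,
                 intercepts = setNames(as.numeric(intercepts), periods),
                 beta_age = beta_age, beta_sex = beta_sex),
            class = "cf_params")
}

phenotypic_cov <- function(p) p$sigma_a + p$sigma_c + p$sigma_e

#' @export
print.cf_params <- function(x, digits = 3, ...) {
  cat("Correlated-factors components over periods:",
      paste(x$periods, collapse = ", "), "\n")
  for (nm in c("sigma_a", "sigma_c", "sigma_e")) {
    cat(toupper(substr(nm, 7, 7)), ":\n")
    print(round(x[[nm]], digits))
  }
  invisible(x)
}

#' Default correlated-factors generating values for child wellbeing
#'
#' Component matrices over the four pandemic periods (pre, early, late, post)
#' set to reported maximum-likelihood estimates for parent-rated child
#' wellbeing on the Cantril ladder: e.g. shared-environment variance 0.52
#' pre-pandemic rising to 0.86 early in the pandemic. Per-period mean levels
#' and small age/sex effects complete the generating model.
#'
#' @return A [cf_params()] object.
#' @export
cf_params_wellbeing <- function() {
  a <- matrix(c(0.38, 0.21, 0.08, 0.07,
                0.21, 0.39, 0.15, 0.10,
                0.08, 0.15, 0.34, 0.11,
                0.07, 0.10, 0.11, 0.38), 4, 4)
  c_ <- matrix(c(0.52, 0.21, 0.33, 0.35,
                 0.21, 0.86, 0.28, 0.36,
                 0.33, 0.28, 0.80, 0.40,
                 0.35, 0.36, 0.40, 0.50), 4, 4)
  e <- matrix(c(0.17, 0.02, 0.00, 0.07,
                0.02, 0.15, 0.04, 0.04,
                0.00, 0.04, 0.18, 0.06,
                0.07, 0.04, 0.06, 0.23), 4, 4)
  cf_params(a, c_, e,
            intercepts = c(pre = 8.5, early = 8.2, late = 7.9, post = 8.2),
            beta_age = -0.02, beta_sex = 0.05)
}

#' Psychometric multi-rater variance components
#'
#' Each parent's rating of a child is the sum of a common latent child
#' phenotype (seen by both raters; the rater-agreement part) and a
#' rater-specific part (the disagreement part), each with its own A/C/E
#' decomposition. The rater-specific shared-environment components (`C_m`,
#' `C_f`) are the rater-bias components: a systematic rating tendency shared
#' across both twins by one rater.
#'
#' @param common [ace_params()] of the latent common phenotype.
#' @param mother,father [ace_params()] of the rater-specific parts.
#' @return Object of class `multirater_params`.
#' @export
multirater_params <- function(common, mother, father) {
  for (p in list(common, mother, father)) {
    stopifnot(inherits(p, "ace_params"))
    if (p$d2 != 0) stop("the psychometric model uses ACE components only (d2 = 0)")
  }
  structure(list(common = common, mother = mother, father = father),
            class = "multirater_params")
}

#' @export
print.multirater_params <- function(x, ...) {
  cat("Psychometric multi-rater components\n")
  cat(sprintf("  common : A=%.3f C=%.3f E=%.3f\n", x$common$a2, x$common$c2, x$common$e2))
  cat(sprintf("  mother : A=%.3f C=%.3f E=%.3f (rater-specific)\n",
              x$mother$a2, x$mother$c2, x$mother$e2))
  cat(sprintf("  father : A=%.3f C=%.3f E=%.3f (rater-specific)\n",
              x$father$a2, x$father$c2, x$father$e2))
  invisible(x)
}

#' Default multi-rater generating values per pandemic period
#'
#' Scenario parameter sets calibrated so that the implied same-twin
#' cross-rater correlation, twin correlations, and the common-view and
#' rater-bias shares reproduce reported values for parent-rated child
#' wellbeing in each pandemic period (e.g. cross-rater correlation 0.50
#' pre-pandemic and mother-specific shared-environment share 47% of
#' mother-rated variance early in the pandemic). Rater totals are normalized
#' to variance 1.
#'
#' @param period one of `"pre"`, `"early"`, `"late"`, `"post"`.
#' @return A [multirater_params()] object.
#' @export
multirater_params_wellbeing <- function(period = c("pre", "early", "late", "post")) {
  period <- match.arg(period)
  sets <- list(
    pre   = list(common = c(0.18, 0.24, 0.08),
                 mother = c(0.14, 0.27, 0.09),
                 father = c(0.08, 0.33, 0.09)),
    early = list(common = c(0.13, 0.16, 0.06),
                 mother = c(0.13, 0.47, 0.05),
                 father = c(0.17, 0.39, 0.09)),
    late  = list(common = c(0.10, 0.20, 0.10),
                 mother = c(0.16, 0.40, 0.04),
                 father = c(0.12, 0.39, 0.09)),
    post  = list(common = c(0.16, 0.17, 0.10),
                 mother = c(0.39, 0.16, 0.02),
                 father = c(0.15, 0.36, 0.06)))
  s <- sets[[period]]
  multirater_params(common = ace_params(s$common[1], s$common[2], s$common[3]),
                    mother = ace_params(s$mother[1], s$mother[2], s$mother[3]),
                    father = ace_params(s$father[1], s$father[2], s$father[3]))
}

#' Random-intercept mixed-model specification
#'
#' Fixed effects for the wellbeing mean model `Y = (b1 + u_i) + b2*wave +
#' b3*sex + b4*age + b5*PEA + b6*rater + e`, with wave categorical (baseline
#' reference), female vs male, age in years, parental educational attainment
#' (low/middle vs high), father vs mother rater, plus random-intercept and
#' residual variances. `var_family` applies only to twin (nested) designs.
#'
#' @param intercept intercept at the reference levels, age 0.
#' @param wave named vector of per-wave offsets relative to the reference wave.
#' @param sex_female,age,pea_low,pea_middle,rater_father fixed effects.
#' @param var_family,var_individual,var_residual variance components (>= 0).
#' @return Object of class `lmm_spec`.
#' @export
lmm_spec <- function(intercept, wave, sex_female = 0, age = 0,
                     pea_low = 0, pea_middle = 0, rater_father = 0,
                     var_family = 0, var_individual = 0, var_residual = 1) {
  stopifnot(var_family >= 0, var_individual >= 0, var_residual >= 0,
            !is.null(names(wave)))
  structure(list(intercept = intercept, wave = wave, sex_female = sex_female,
                 age = age, pea_low = pea_low, pea_middle = pea_middle,
                 rater_father = rater_father, var_family = var_family,
                 var_individual = var_individual, var_residual = var_residual),
            class = "lmm_spec")
}

#' Mixed-model generating values for the three study-like cohorts
#'
#' Fixed effects set to reported mixed-model coefficients for parent-rated
#' child wellbeing: a longitudinal population twin cohort (`ntr`, baseline
#' wave 0 reference), a cross-sectional population cohort (`klik`, wave 2
#' reference) and a cross-sectional clinical cohort (`dreams`, wave 2
#' reference, lower mean wellbeing, strong negative age effect). Variance
#' components are plausible values for parent-rated wellbeing (twin
#' intraclass correlation about 0.57 in the twin cohort).
#'
#' @name lmm_spec_cohorts
#' @return An [lmm_spec()] object.
#' @export
lmm_spec_ntr <- function() {
  lmm_spec(intercept = 8.7,
           wave = c(`1` = -0.593, `2` = 0.007, `3` = -0.722, `4` = -0.434,
                    `5` = -0.286, `6` = -0.339),
           sex_female = 0.047, age = -0.021,
           pea_low = -0.168, pea_middle = -0.112, rater_father = -0.046,
           var_family = 0.35, var_individual = 0.25, var_residual = 0.45)
}

#' @rdname lmm_spec_cohorts
#' @export
lmm_spec_klik <- function() {
  lmm_spec(intercept = 8.6,
           wave = c(`3` = -0.098, `4` = -0.106, `5` = -0.046, `6` = -0.114,
                    `7` = -0.178),
           sex_female = 0.081, age = 0.007,
           pea_low = -0.254, pea_middle = -0.123, rater_father = 0.011,
           var_family = 0, var_individual = 0.30, var_residual = 0.90)
}

#' @rdname lmm_spec_cohorts
#' @export
lmm_spec_dreams <- function() {
  lmm_spec(intercept = 8.5,
           wave = c(`3` = -0.421, `4` = -0.085, `5` = 0.059, `6` = 0.205,
                    `7` = 0.215),
           sex_female = -0.344, age = -0.143,
           pea_low = 0.280, pea_middle = 0.039, rater_father = 0.200,
           var_family = 0, var_individual = 0.30, var_residual = 0.90)
}
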