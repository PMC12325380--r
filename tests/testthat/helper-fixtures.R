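# Shared fixtures, built in code. The printed component matrices are the
# reported four-period A/C/E estimates for parent-rated child wellbeing used
# as generating values throughout the suite.

printed_components <- function() {
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
  # phenotypic (co)variances as printed in the source report (off-diagonal
  # covariances are reported independently of the component sums)
  p <- matrix(c(1.06, 0.45, 0.41, 0.49,
                0.45, 1.40, 0.47, 0.49,
                0.41, 0.47, 1.32, 0.57,
                0.49, 0.49, 0.57, 1.10), 4, 4)
  pn <- c("pre", "early", "late", "post")
  dimnames(a) <- dimnames(c_) <- dimnames(e) <- dimnames(p) <- list(pn, pn)
  list(A = a, C = c_, E = e, P = p)
}

# A one-period univariate generating model (handy for cheap univariate fits).
univariate_config <- function(a2, c2, e2, n_mz, n_dz, seed,
                              intercept = 8, beta_age = 0, beta_sex = 0) {
  simulation_config(
    n_mz_pairs = n_mz, n_dz_pairs = n_dz,
    cf_params = cf_params(matrix(a2), matrix(c2), matrix(e2),
                          periods = "pre", intercepts = intercept,
                          beta_age = beta_age, beta_sex = beta_sex),
    seed = seed)
}

# Random PSD matrix with variances on a wellbeing-like scale.
random_psd <- function(k, scale = 0.5) {
  m <- matrix(rnorm(k * k, sd = scale), k, k)
  crossprod(m) / k + diag(0.05, k)
}

default_mr_params <- function() {
  pn <- c("pre", "early", "late", "post")
  setNames(lapply(pn, multirater_params_wellbeing), pn)
}

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("|%.4f - %.4f| <= %.4f", value, target, tol))
}
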