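# Correlated factors model: expected covariance algebra, derived quantities
# and simulation-recovery behavior.

test_that("expected covariance blocks follow the kinship algebra", {
  pc <- printed_components()
  params <- cf_params(pc$A, pc$C, pc$E)
  mz <- build_cf_expected_cov(params, "MZ")
  dz <- build_cf_expected_cov(params, "DZ")
  expect_true(isSymmetric(mz) && isSymmetric(dz))
  expect_equal(mz[1, 1], 0.38 + 0.52 + 0.17) # within-twin pre-period variance
  expect_equal(mz[1:4, 5:8] - dz[1:4, 5:8], 0.5 * pc$A, ignore_attr = TRUE)

  z <- matrix(0, 4, 4)
  blockdiag <- build_cf_expected_cov(cf_params(z, z, pc$E), "MZ")
  expect_equal(blockdiag[1:4, 5:8], z, ignore_attr = TRUE)
})

test_that("component correlations reproduce the printed derived values", {
  pc <- printed_components()
  der <- component_correlations(cf_params(pc$A, pc$C, pc$E))
  expect_equal(round(der$rA["pre", "early"], 2), 0.55)
  expect_equal(round(der$rA["pre", "late"], 2), 0.22)
  expect_equal(round(der$rC["pre", "post"], 2), 0.69)
  expect_equal(round(correlation_from_components(0.21, 0.38, 0.39), 2), 0.55)

  diag_only <- cf_params(diag(4) * 0.3, diag(4) * 0.3, diag(4) * 0.3)
  dd <- component_correlations(diag_only)
  expect_equal(dd$rA[upper.tri(dd$rA)], rep(0, 6))

  degenerate <- cf_params(matrix(0, 2, 2), diag(2), diag(2),
                          periods = c("pre", "early"))
  expect_true(all(is.na(component_correlations(degenerate)$rA)))
})

test_that("standardized shares use the component-sum phenotypic variance and sum to 1", {
  pc <- printed_components()
  std <- standardize_components(cf_params(pc$A, pc$C, pc$E))
  expect_equal(round(std$C["pre", "pre"], 2), 0.49)
  expect_equal(std$A + std$C + std$E, matrix(1, 4, 4), ignore_attr = TRUE)

  set.seed(17)
  rnd <- cf_params(random_psd(4), random_psd(4), random_psd(4))
  srnd <- standardize_components(rnd)
  expect_equal(srnd$A + srnd$C + srnd$E, matrix(1, 4, 4),
               ignore_attr = TRUE, tolerance = 1e-9)

  all_c <- standardize_components(cf_params(matrix(0, 4, 4) ,
                                            pc$C, matrix(0, 4, 4)))
  expect_equal(all_c$C, matrix(1, 4, 4), ignore_attr = TRUE)
})

test_that("report tables carry the printed phenotypic correlations", {
  pc <- printed_components()
  # correlations reconstructed from the printed phenotypic (co)variances
  rp <- correlation_from_components(pc$P["pre", "early"],
                                    pc$P["pre", "pre"], pc$P["early", "early"])
  expect_equal(round(rp, 2), 0.37)
  allr <- outer(1:4, 1:4, Vectorize(function(i, j) {
    correlation_from_components(pc$P[i, j], pc$P[i, i], pc$P[j, j])
  }))
  expect_equal(round(max(allr[upper.tri(allr)]), 2), 0.47)

  tabs <- reproduce_tables(cf_params(pc$A, pc$C, pc$E))
  expect_setequal(unique(tabs$unstandardized$component),
                  c("phenotypic", "A", "C", "E"))
  pre_c <- tabs$standardized[tabs$standardized$component == "C" &
                               tabs$standardized$period_i == "pre" &
                               tabs$standardized$period_j == "pre", "share"]
  expect_equal(pre_c, 0.49)

  ident <- reproduce_tables(cf_params(diag(4), diag(4), diag(4) * 0.5))
  off <- ident$unstandardized[ident$unstandardized$period_i !=
                                ident$unstandardized$period_j, ]
  expect_true(all(off$correlation == 0))
})

test_that("the fit recovers a generating model and is invariant to twin relabeling", {
  cfg <- simulation_config(n_mz_pairs = 700, n_dz_pairs = 700, seed = 23)
  rows <- simulate_twin_cohort(cfg)
  cf <- fit_correlated_factors(rows, n_restarts = 1)
  expect_true(cf$fit$converged)
  gen <- cf_params_wellbeing()
  expect_within(cf$params$sigma_c["pre", "pre"], gen$sigma_c["pre", "pre"], 0.12)
  expect_within(cf$params$sigma_a["early", "early"], gen$sigma_a["early", "early"], 0.15)
  expect_within(cf$params$beta_sex, gen$beta_sex, 0.08)

  # swapping twin-1/twin-2 labels leaves the likelihood unchanged
  swapped <- rows
  swapped$individual_id <- paste0(rows$family_id, "_",
                                  3 - as.integer(sub(".*_", "", rows$individual_id)))
  cf2 <- fit_correlated_factors(swapped, n_restarts = 1)
  expect_equal(cf2$fit$minus2ll, cf$fit$minus2ll, tolerance = 1e-6)
})

test_that("estimates stay unbiased under MCAR dropout at the overlap level of the study", {
  cfg <- simulation_config(n_mz_pairs = 1500, n_dz_pairs = 1500, seed = 25,
                           missingness = missingness_spec(pairwise_overlap = 0.4))
  rows <- simulate_twin_cohort(cfg)
  cf <- fit_correlated_factors(rows, n_restarts = 1)
  gen <- cf_params_wellbeing()
  expect_within(cf$params$sigma_c["pre", "pre"], gen$sigma_c["pre", "pre"], 0.12)
  expect_within(cf$params$sigma_c["early", "early"], gen$sigma_c["early", "early"], 0.15)
  expect_within(cf$params$sigma_e["pre", "pre"], gen$sigma_e["pre", "pre"], 0.05)
})

test_that("a generating model without shared environment piles C at the zero boundary", {
  k <- 4
  zero <- matrix(0, k, k)
  cfg <- simulation_config(
    n_mz_pairs = 1500, n_dz_pairs = 1500,
    cf_params = cf_params(diag(0.4, k), zero, diag(0.4, k),
                          intercepts = rep(8, k)),
    seed = 27)
  rows <- simulate_twin_cohort(cfg)
  cf <- fit_correlated_factors(rows, n_restarts = 1)
  # sampling noise truncated at the boundary: entries hug zero
  expect_lt(max(diag(cf$params$sigma_c)), 0.08)
  expect_lt(mean(diag(cf$params$sigma_c)), 0.04)
})

test_that("periods without cross-twin information are flagged unidentified", {
  cfg <- simulation_config(n_mz_pairs = 150, n_dz_pairs = 150, seed = 29)
  rows <- simulate_twin_cohort(cfg)
  # remove every second twin's late-period rating: no complete late pairs
  drop <- rows$period == "late" & grepl("_2$", rows$individual_id)
  cf <- fit_correlated_factors(rows[!drop, ], n_restarts = 1)
  expect_true("late" %in% cf$unidentified)
})
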