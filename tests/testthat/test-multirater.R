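# Psychometric multi-rater model: covariance algebra, view decomposition,
# constraint testing and the rater-bias inflation of single-rater C.

test_that("expected multi-rater covariance follows the psychometric algebra", {
  prm <- multirater_params(common = ace_params(0.2, 0.3, 0.1),
                           mother = ace_params(0.1, 0.2, 0.1),
                           father = ace_params(0.1, 0.2, 0.1))
  S <- build_multirater_expected_cov(prm, "MZ")
  expect_equal(S["m1", "m1"], 1.0)
  expect_equal(S["m1", "f1"], 0.6)
  expect_equal(S["m1", "m2"], 0.8)
  expect_equal(S["m1", "f2"], 0.5)
  expect_true(isSymmetric(S))

  # perfect agreement: no specific components
  tiny <- 1e-10
  pure <- multirater_params(common = ace_params(0.3, 0.3, 0.2),
                            mother = ace_params(0, 0, tiny),
                            father = ace_params(0, 0, tiny))
  Sp <- build_multirater_expected_cov(pure, "DZ")
  expect_equal(Sp["m1", "f1"], Sp["m1", "m1"], tolerance = 1e-8)
})

test_that("psychometric invariants hold for random parameter sets", {
  set.seed(63)
  for (i in 1:10) {
    prm <- multirater_params(
      common = ace_params(runif(1, 0, 0.5), runif(1, 0, 0.5), runif(1, 0.05, 0.5)),
      mother = ace_params(runif(1, 0, 0.4), runif(1, 0, 0.4), runif(1, 0.05, 0.4)),
      father = ace_params(runif(1, 0, 0.4), runif(1, 0, 0.4), runif(1, 0.05, 0.4)))
    mz <- build_multirater_expected_cov(prm, "MZ")
    dz <- build_multirater_expected_cov(prm, "DZ")
    # same-twin cross-rater covariance carries no kinship term
    expect_equal(mz["m1", "f1"], dz["m1", "f1"])
    # agreement cannot exceed either rater's total variance
    expect_lte(mz["m1", "f1"], min(mz["m1", "m1"], mz["f1", "f1"]))
    # MZ - DZ contrasts identify A and A_r
    expect_equal(mz["m1", "m2"] - dz["m1", "m2"],
                 0.5 * (prm$common$a2 + prm$mother$a2))
    expect_equal(mz["m1", "f2"] - dz["m1", "f2"], 0.5 * prm$common$a2)
    # the two identifying constraints hold by construction
    expect_equal(mz["m1", "f2"], mz["m2", "f1"])
    sh <- decompose_views(prm)
    expect_equal(sum(sh$mother$shares), 1, tolerance = 1e-9)
    expect_equal(sh$mother$common_share + sh$mother$specific_share, 1,
                 tolerance = 1e-9)
  }
})

test_that("view decomposition: shares, bias index and degenerate cases", {
  prm <- multirater_params_wellbeing("pre")
  v <- decompose_views(prm)
  expect_equal(v$mother$common_share, 0.50)
  expect_equal(v$mother$bias_share, 0.27)
  expect_equal(v$combined_common_share, 0.50 / 1.50, tolerance = 1e-9)

  all_common <- multirater_params(common = ace_params(0.4, 0.3, 0.3),
                                  mother = ace_params(0, 0, 1e-12),
                                  father = ace_params(0, 0, 1e-12))
  va <- decompose_views(all_common)
  expect_equal(va$mother$common_share, 1, tolerance = 1e-9)
  expect_equal(va$mother$bias_share, 0)
})

test_that("the psychometric fit recovers its own generating components", {
  cfg <- simulation_config(n_mz_pairs = 1500, n_dz_pairs = 1500,
                           multirater = default_mr_params(), seed = 65)
  rows <- simulate_twin_cohort(cfg)
  fit <- fit_psychometric(rows, "pre", n_restarts = 2)
  expect_true(fit$fit$converged)
  gen <- multirater_params_wellbeing("pre")
  for (part in c("common", "mother", "father")) {
    for (comp in c("a2", "c2", "e2")) {
      expect_within(fit$params[[part]][[comp]], gen[[part]][[comp]], 0.06)
    }
  }
  # model-implied matrices agree with the constrained saturated fit
  sat <- fit_constrained_saturated(rows, "pre", n_restarts = 1)
  S_psy <- build_multirater_expected_cov(fit$params, "MZ")
  expect_within(sat$matrices$MZ[1, 2], S_psy["m1", "f1"], 0.03)
  expect_within(sat$matrices$MZ[1, 3], S_psy["m1", "m2"], 0.04)
})

test_that("constraint test keeps true constraints and rejects violated ones", {
  # generating model satisfies both constraints: p-values behave like a null
  set.seed(67)
  seeds <- sample.int(1e6, 25)
  ps <- vapply(seeds, function(s) {
    cfg <- simulation_config(n_mz_pairs = 350, n_dz_pairs = 350,
                             multirater = default_mr_params(), seed = s)
    rows <- simulate_twin_cohort(cfg)
    fit_constrained_saturated(rows, "pre", n_restarts = 1)$lrt$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2) # type-I error near nominal
  expect_gt(mean(ps), 0.3)         # p-values roughly uniform under the null

  # zygosity-dependent agreement violates constraint (1): mix two cohorts
  cfg_mz <- simulation_config(n_mz_pairs = 1500, n_dz_pairs = 2,
                              multirater = default_mr_params(), seed = 68)
  early_all <- setNames(lapply(default_periods(),
                               function(p) multirater_params_wellbeing("early")),
                        default_periods())
  cfg_dz <- simulation_config(n_mz_pairs = 2, n_dz_pairs = 1500,
                              multirater = early_all, seed = 69)
  rows_mz <- simulate_twin_cohort(cfg_mz)
  rows_dz <- simulate_twin_cohort(cfg_dz)
  rows_dz$family_id <- paste0("dz", rows_dz$family_id)
  rows_dz$individual_id <- paste0("dz", rows_dz$individual_id)
  mixed <- rbind(rows_mz[rows_mz$zygosity == "MZ", ],
                 rows_dz[rows_dz$zygosity == "DZ", ])
  bad <- fit_constrained_saturated(mixed, "pre", n_restarts = 1)
  expect_lt(bad$lrt$p, 1e-4)
  expect_false(bad$constraints_satisfied)
})

test_that("families with a single responding rater still inform the fit", {
  cfg <- simulation_config(n_mz_pairs = 1200, n_dz_pairs = 1200,
                           multirater = default_mr_params(),
                           missingness = missingness_spec(
                             rater_prob = list(mother = 0.9, father = 0.5)),
                           seed = 71)
  rows <- simulate_twin_cohort(cfg)
  fit <- fit_psychometric(rows, "pre", n_restarts = 1)
  gen <- multirater_params_wellbeing("pre")
  expect_within(fit$params$common$c2, gen$common$c2, 0.08)
  expect_within(fit$params$mother$c2, gen$mother$c2, 0.08)
})

test_that("rater bias inflates shared environment in a single-rater analysis", {
  # generating mother-specific C = 0.27 on top of common C = 0.24: a
  # mother-only ACE fit attributes the bias to C
  cfg <- simulation_config(n_mz_pairs = 2000, n_dz_pairs = 2000,
                           multirater = default_mr_params(), seed = 73)
  rows <- simulate_twin_cohort(cfg)
  single <- fit_model("ACE", rows, period = "pre", rater = "mother",
                      n_restarts = 1, se = FALSE)
  gen <- multirater_params_wellbeing("pre")
  expect_gt(single$estimates[["c2"]], gen$common$c2 + 0.15)
  expect_within(single$estimates[["c2"]], gen$common$c2 + gen$mother$c2, 0.06)
})
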