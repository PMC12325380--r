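# Random-intercept mixed model: exact limits, oracle agreement, invariances,
# marginal means and baseline selection.

test_that("with all variances zero the fixed effects are recovered exactly", {
  spec <- lmm_spec(intercept = 8, wave = c(`1` = -0.5, `2` = 0.2),
                   sex_female = 0.1, age = -0.02, pea_low = -0.2,
                   pea_middle = -0.1, rater_father = -0.05,
                   var_family = 0, var_individual = 0, var_residual = 0)
  design <- lmm_design("twin", 300, waves = 0:2, participation = 1,
                       father_prob = 0.3)
  rows <- simulate_lmm_cohort(spec, design, seed = 3)
  fit <- fit_random_intercept_lmm(rows, nesting = "none")
  b <- coef(fit)
  expect_equal(unname(b["(Intercept)"]), 8, tolerance = 1e-8)
  expect_equal(unname(b["wave1"]), -0.5, tolerance = 1e-8)
  expect_equal(unname(b["sexfemale"]), 0.1, tolerance = 1e-8)
  expect_equal(unname(b["age"]), -0.02, tolerance = 1e-8)
  expect_equal(unname(b["raterfather"]), -0.05, tolerance = 1e-8)
})

test_that("fixed effects agree with the nlme oracle on random small datasets", {
  set.seed(83)
  seeds <- sample.int(1e6, 50)
  for (s in seeds) {
    rows <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(80), seed = s)
    mine <- fit_random_intercept_lmm(rows)
    rows$sexf <- as.numeric(rows$sex == "female")
    rows$low <- as.numeric(rows$pea == "low")
    rows$mid <- as.numeric(rows$pea == "middle")
    rows$fa <- as.numeric(rows$rater == "father")
    oracle <- nlme::lme(wellbeing ~ factor(wave) + sexf + age + low + mid + fa,
                        random = ~ 1 | family_id / individual_id,
                        data = rows, method = "ML")
    expect_lt(max(abs(coef(mine) - nlme::fixef(oracle))), 1e-4)
    expect_equal(mine$loglik, as.numeric(stats::logLik(oracle)), tolerance = 1e-6)
  }
})

test_that("intraclass correlation matches the variance ratio in the intercept-only model", {
  spec <- lmm_spec(intercept = 8, wave = c(`1` = 0), var_family = 0.4,
                   var_individual = 0.2, var_residual = 0.4)
  design <- lmm_design("twin", 4000, waves = 0:3, participation = 1)
  rows <- simulate_lmm_cohort(spec, design, seed = 85)
  fit <- fit_random_intercept_lmm(rows, covariates = character(0))
  v <- fit$variances
  expect_within(v[["var_family"]], 0.4, 0.04)
  expect_within(v[["var_individual"]], 0.2, 0.04)
  expect_within(v[["var_residual"]], 0.4, 0.02)
  # empirical cross-twin correlation of individual means ~ family share
  icc <- v[["var_family"]] / sum(v)
  ind_mean <- aggregate(wellbeing ~ individual_id + family_id, rows, mean)
  ind_mean <- ind_mean[order(ind_mean$family_id, ind_mean$individual_id), ]
  m1 <- ind_mean$wellbeing[seq(1, nrow(ind_mean), 2)]
  m2 <- ind_mean$wellbeing[seq(2, nrow(ind_mean), 2)]
  expect_within(cor(m1, m2),
                0.4 / (0.4 + 0.2 + 0.4 / length(unique(rows$wave))), 0.04)
  expect_within(icc, 0.4, 0.04)
})

test_that("the fit is invariant to row and family shuffling", {
  rows <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(200), seed = 87)
  fit1 <- fit_random_intercept_lmm(rows)
  set.seed(88)
  fit2 <- fit_random_intercept_lmm(rows[sample(nrow(rows)), ])
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-7)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-7)
})

test_that("estimated marginal means track the wave offsets and ignore recoding", {
  rows <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(3000), seed = 89)
  fit <- fit_random_intercept_lmm(rows)
  emm <- estimated_marginal_means(fit)
  expect_within(emm$emm[emm$wave == 1] - emm$emm[emm$wave == 0], -0.593, 0.05)
  # reference recoding leaves the marginal means unchanged
  fit2 <- fit_random_intercept_lmm(rows, reference_wave = 3)
  emm2 <- estimated_marginal_means(fit2)
  expect_equal(emm$emm, emm2$emm, tolerance = 1e-6)
  expect_error(estimated_marginal_means(fit, waves = 99), "absent")

  # intercept-only model: every wave's marginal mean is the model grand mean
  fit0 <- fit_random_intercept_lmm(rows, covariates = character(0))
  emm0 <- estimated_marginal_means(fit0)
  expect_equal(length(unique(round(emm0$emm, 10))), 1)
  expect_within(emm0$emm[1], mean(rows$wellbeing), 0.05)
})

test_that("singleton cohorts flag the near-unidentified individual intercept", {
  rows <- simulate_lmm_cohort(lmm_spec_dreams(), lmm_design_dreams(400), seed = 91)
  expect_warning(fit <- fit_random_intercept_lmm(rows, nesting = "individual"),
                 "near-unidentified")
  expect_true(fit$near_unidentified_individual)
  # the fixed effects remain well determined (OLS equivalent)
  ols <- fit_random_intercept_lmm(rows, nesting = "none")
  expect_equal(coef(fit)[["age"]], coef(ols)[["age"]], tolerance = 1e-3)
})

test_that("rank-deficient designs name the aliased columns", {
  rows <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(50), seed = 93)
  rows$rater <- ifelse(rows$sex == "female", "father", "mother") # aliased
  expect_error(fit_random_intercept_lmm(rows), "raterfather")
  rows2 <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(50), seed = 94)
  rows2$rater <- "mother"
  expect_message(fit_random_intercept_lmm(rows2), "raterfather")
})

test_that("baseline selection keeps the latest pre-pandemic record", {
  rows <- data.frame(
    family_id = "f1", individual_id = c("a", "a", "a", "b"),
    zygosity = "MZ", wave = c(0, 0, 1, 1), period = c("pre", "pre", "early", "early"),
    rater = "mother", sex = "female", age = 10, pea = "high",
    wellbeing = c(7, 8, 6, 5), year = c(2012, 2018, 2020, 2020))
  sel <- select_baseline(rows)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$wellbeing, 8) # the 2018 record
  expect_length(attr(sel, "ties"), 0)

  none <- select_baseline(rows[rows$wave > 0, ])
  expect_equal(nrow(none), 0)

  tie <- rows
  tie$year <- c(2018, 2018, 2020, 2020)
  sel2 <- select_baseline(tie)
  expect_equal(sel2$wellbeing, 7) # first record in table order
  expect_equal(attr(sel2, "ties"), "a")
})
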