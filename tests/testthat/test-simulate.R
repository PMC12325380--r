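# Synthetic-data generator: determinism, latent twin structure, missingness
# and Cantril discretization.

test_that("identical seeds give byte-identical cohorts; different seeds differ", {
  cfg <- simulation_config(n_mz_pairs = 40, n_dz_pairs = 40, seed = 42)
  r1 <- simulate_twin_cohort(cfg)
  r2 <- simulate_twin_cohort(cfg)
  expect_identical(r1, r2)
  cfg2 <- simulation_config(n_mz_pairs = 40, n_dz_pairs = 40, seed = 43)
  expect_false(identical(r1$wellbeing, simulate_twin_cohort(cfg2)$wellbeing))

  l1 <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(50), seed = 7)
  l2 <- simulate_lmm_cohort(lmm_spec_ntr(), lmm_design_ntr(50), seed = 7)
  expect_identical(l1, l2)
})

test_that("MZ twins are identical when all variance is additive genetic", {
  k <- 4
  cfg <- simulation_config(
    n_mz_pairs = 60, n_dz_pairs = 1,
    cf_params = cf_params(diag(k), matrix(0, k, k), matrix(0, k, k),
                          intercepts = rep(8, k)),
    seed = 5)
  rows <- simulate_twin_cohort(cfg)
  mz <- rows[rows$zygosity == "MZ", ]
  for (p in unique(mz$period)) {
    w <- twin_pairs(mz, period = p)
    expect_equal(w$y1, w$y2, tolerance = 1e-12)
  }
})

test_that("cross-twin covariance matches the closed form a2+c2 (MZ) and a2/2+c2 (DZ)", {
  cfg <- univariate_config(0.38, 0.52, 0.17, n_mz = 50000, n_dz = 50000, seed = 301)
  rows <- simulate_twin_cohort(cfg)
  w <- twin_pairs(rows, period = "pre")
  cov_z <- function(z) {
    x <- w[w$zygosity == z, ]
    cov(x$y1, x$y2)
  }
  # 3 Monte-Carlo standard errors of a covariance at n = 50,000 is ~0.02
  expect_within(cov_z("MZ"), 0.90, 0.02)
  expect_within(cov_z("DZ"), 0.71, 0.02)

  # with A = C = 0 only non-shared environment remains
  cfg0 <- univariate_config(0, 0, 1, n_mz = 20000, n_dz = 20000, seed = 302)
  w0 <- twin_pairs(simulate_twin_cohort(cfg0), period = "pre")
  expect_within(cov(w0$y1[w0$zygosity == "MZ"], w0$y2[w0$zygosity == "MZ"]), 0, 0.025)
})

test_that("empirical covariance matches the model-implied covariance for random PSD sets", {
  set.seed(88)
  for (rep in 1:3) {
    prm <- multirater_params(
      common = ace_params(runif(1, 0.1, 0.4), runif(1, 0.1, 0.4), runif(1, 0.05, 0.3)),
      mother = ace_params(runif(1, 0.05, 0.3), runif(1, 0.05, 0.3), runif(1, 0.05, 0.2)),
      father = ace_params(runif(1, 0.05, 0.3), runif(1, 0.05, 0.3), runif(1, 0.05, 0.2)))
    cfg <- simulation_config(
      n_mz_pairs = 4000, n_dz_pairs = 4000,
      multirater = list(pre = prm, early = prm, late = prm, post = prm),
      seed = 400 + rep)
    rows <- simulate_twin_cohort(cfg)
    d <- rows[rows$period == "pre", ]
    for (z in c("MZ", "DZ")) {
      S_exp <- build_multirater_expected_cov(prm, z)
      dz <- d[d$zygosity == z, ]
      twin <- ave(seq_len(nrow(dz)), dz$family_id,
                  FUN = function(i) as.integer(factor(dz$individual_id[i])))
      wide <- matrix(NA_real_, length(unique(dz$family_id)), 4)
      ri <- as.integer(factor(dz$family_id))
      ci <- (twin - 1) * 2 + match(dz$rater, c("mother", "father"))
      wide[cbind(ri, ci)] <- dz$wellbeing
      S_emp <- cov(wide)
      for (i in 1:4) for (j in 1:4) {
        mc_se <- sqrt((S_exp[i, i] * S_exp[j, j] + S_exp[i, j]^2) / nrow(wide))
        expect_within(S_emp[i, j], S_exp[i, j], 3.5 * mc_se)
      }
    }
  }
})

test_that("marginal rating variance is the sum of common and specific components", {
  prm <- multirater_params_wellbeing("pre")
  cfg <- simulation_config(n_mz_pairs = 8000, n_dz_pairs = 8000,
                           multirater = default_mr_params(), seed = 55)
  rows <- simulate_twin_cohort(cfg)
  m_pre <- rows[rows$period == "pre" & rows$rater == "mother", ]
  tot <- (prm$common$a2 + prm$common$c2 + prm$common$e2 +
            prm$mother$a2 + prm$mother$c2 + prm$mother$e2)
  # subtract the small mean-model (age, sex) contribution by residualizing
  res <- resid(lm(wellbeing ~ age + sex, data = m_pre))
  expect_within(var(res), tot, 0.03)
})

test_that("missingness: identity, rater shutdown, and pairwise-overlap targeting", {
  cfg <- simulation_config(n_mz_pairs = 100, n_dz_pairs = 100,
                           multirater = default_mr_params(), seed = 9)
  rows <- simulate_twin_cohort(cfg)
  expect_identical(apply_missingness(rows, missingness_spec(1, 1), seed = 3), rows)

  no_dad <- apply_missingness(rows, missingness_spec(1, list(mother = 1, father = 0)),
                              seed = 3)
  expect_false("father" %in% no_dad$rater)
  expect_equal(sum(no_dad$rater == "mother"), sum(rows$rater == "mother"))

  big <- simulation_config(n_mz_pairs = 3000, n_dz_pairs = 3000, seed = 10)
  rows2 <- simulate_twin_cohort(big)
  miss <- apply_missingness(rows2, missingness_spec(pairwise_overlap = 0.4), seed = 11)
  seen <- function(p) unique(miss$individual_id[miss$period == p])
  frac_both <- length(intersect(seen("early"), seen("late"))) / 12000
  expect_within(frac_both, 0.4, 0.03)

  # both twins share the baseline-availability flag
  pre_fams <- miss[miss$period == "pre", ]
  n_by_fam <- table(table(pre_fams$family_id))
  expect_false("1" %in% names(n_by_fam))
})

test_that("missingness is deterministic given its seed", {
  cfg <- simulation_config(n_mz_pairs = 80, n_dz_pairs = 80, seed = 12)
  rows <- simulate_twin_cohort(cfg)
  ms <- missingness_spec(obs_prob = 0.6, rater_prob = 0.7)
  expect_identical(apply_missingness(rows, ms, seed = 4),
                   apply_missingness(rows, ms, seed = 4))
})

test_that("Cantril discretization rounds, clips, stays monotone, adds ~1/12 variance", {
  expect_equal(discretize_cantril(8.4), 8L)
  expect_equal(discretize_cantril(-1.2), 0L)
  expect_equal(discretize_cantril(12.7), 10L)
  x <- sort(runif(200, -2, 12))
  expect_true(all(diff(discretize_cantril(x)) >= 0))
  set.seed(14)
  lat <- rnorm(200000, mean = 5, sd = 1)
  expect_within(var(discretize_cantril(lat)), var(lat) + 1 / 12, 0.02)
})

test_that("non-PSD component matrices are rejected with a diagnostic naming the matrix", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2) # indefinite
  expect_error(cf_params(bad, diag(2), diag(2), periods = c("pre", "early")),
               "sigma_a")
  expect_error(cf_params(diag(2), bad, diag(2), periods = c("pre", "early")),
               "sigma_c")
})
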