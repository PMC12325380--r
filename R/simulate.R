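# Synthetic twin-cohort generator. Twin pairs carry latent additive-genetic
# (A), shared-environment (C) and non-shared environment (E) deviates with the
# classical cross-twin correlations (A: 1 in MZ, 0.5 in DZ; C: 1; E: 0), a
# cross-period correlated-factors structure for the common child phenotype,
# and optional per-period rater-specific components for mother and father
# ratings (rater-specific C is fully shared across twins within a rater:
# the rater-bias component).

#' Missingness specification for simulated cohorts
#'
#' Observation of a child in a period and response of a rater in a period are
#' dropped independently, missing-completely-at-random. The first (baseline)
#' period is dropped at the family level so both twins always share the
#' baseline-availability flag; later periods are dropped per child; rater
#' response is dropped per family x rater x period (a parent reports on both
#' twins at once).
#'
#' @param obs_prob probability a child is observed in a period; scalar or
#'   named per period. Ignored if `pairwise_overlap` is given.
#' @param rater_prob probability a rater responds in a period; scalar, named
#'   per rater (`mother`, `father`), or a named list of per-period vectors.
#' @param pairwise_overlap optional target for the expected fraction of
#'   individuals observed in both of any two given periods; translated to a
#'   constant per-period observation probability `sqrt(pairwise_overlap)`.
#' @return Object of class `missingness_spec`.
#' @export
missingness_spec <- function(obs_prob = 1, rater_prob = 1, pairwise_overlap = NULL) {
  if (!is.null(pairwise_overlap)) {
    stopifnot(pairwise_overlap >= 0, pairwise_overlap <= 1)
    obs_prob <- sqrt(pairwise_overlap)
  }
  stopifnot(all(unlist(obs_prob) >= 0), all(unlist(obs_prob) <= 1),
            all(unlist(rater_prob) >= 0), all(unlist(rater_prob) <= 1))
  structure(list(obs_prob = obs_prob, rater_prob = rater_prob),
            class = "missingness_spec")
}

prob_for <- function(p, key) {
  if (is.list(p)) p <- p[[key]] %||% 1
  if (!is.null(names(p)) && key %in% names(p)) unname(p[key]) else unname(p[1])
}

#' Configuration for a simulated twin cohort
#'
#' @param n_mz_pairs,n_dz_pairs pair counts per zygosity (> 0).
#' @param cf_params [cf_params()] generating components for the common child
#'   phenotype across periods, including the mean model.
#' @param multirater optional named list (one [multirater_params()] per
#'   period) of rater-specific components. When supplied, the common-phenotype
#'   variance of each period is taken from `multirater[[period]]$common` and
#'   cross-period common covariances are scaled accordingly; both parents emit
#'   ratings. When `NULL`, only mother ratings of the common phenotype are
#'   emitted (single-rater design).
#' @param missingness optional [missingness_spec()] applied after generation.
#' @param cantril_discretize round and clip scores to the integer 0-10 ladder.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param pea_probs probabilities of low/middle/high parental educational
#'   attainment per family.
#' @param age_range baseline age range (years), uniform per family.
#' @param wave_of_period representative survey wave emitted per period.
#' @param age_offset_years years elapsed from baseline per period.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_mz_pairs, n_dz_pairs,
                              cf_params = cf_params_wellbeing(),
                              multirater = NULL,
                              missingness = NULL,
                              cantril_discretize = FALSE,
                              seed = 1L,
                              pea_probs = c(low = 0.111, middle = 0.372, high = 0.517),
                              age_range = c(7, 12),
                              wave_of_period = c(pre = 0L, early = 1L, late = 3L, post = 5L),
                              age_offset_years = c(pre = 0, early = 1, late = 2, post = 3)) {
  stopifnot(n_mz_pairs > 0, n_dz_pairs > 0, inherits(cf_params, "cf_params"))
  if (!is.null(multirater)) {
    stopifnot(is.list(multirater),
              all(cf_params$periods %in% names(multirater)))
    lapply(multirater, function(p) stopifnot(inherits(p, "multirater_params")))
  }
  if (!is.null(missingness)) stopifnot(inherits(missingness, "missingness_spec"))
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 periods = cf_params$periods,
                 cf_params = cf_params, multirater = multirater,
                 missingness = missingness,
                 cantril_discretize = cantril_discretize,
                 seed = as.integer(seed), pea_probs = pea_probs,
                 age_range = age_range,
                 wave_of_period = wave_of_period[cf_params$periods],
                 age_offset_years = age_offset_years[cf_params$periods]),
            class = "simulation_config")
}

# n draws from N(0, Sigma) via a PSD-safe eigen square root (handles the
# rank-deficient matrices that arise with zero components).
rmvn0 <- function(n, sigma) {
  k <- ncol(sigma)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  f <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  matrix(rnorm(n * k), n, k) %*% t(f)
}

# Cross-twin correlated draws of a k-variate deviate: rho = 1 shares one draw,
# otherwise splits into a shared and a unique part (rho * Sigma shared).
draw_twin_pair <- function(n, sigma, rho) {
  if (rho >= 1) {
    x <- rmvn0(n, sigma)
    list(t1 = x, t2 = x)
  } else if (rho <= 0) {
    list(t1 = rmvn0(n, sigma), t2 = rmvn0(n, sigma))
  } else {
    s <- rmvn0(n, rho * sigma)
    list(t1 = s + rmvn0(n, (1 - rho) * sigma),
         t2 = s + rmvn0(n, (1 - rho) * sigma))
  }
}

#' Simulate a twin cohort with known A/C/E structure
#'
#' Generates MZ and DZ twin pairs whose latent components follow the
#' correlated-factors structure in `config$cf_params` (cross-twin
#' correlations: A 1 for MZ / 0.5 for DZ, C 1, E 0), with one row per child x
#' period x responding rater. With `config$multirater` set, mother and father
#' ratings each add rater-specific A/C/E deviates on top of the common child
#' phenotype; rater-specific C is shared across twins within a rater (rater
#' bias) and rater-specific A carries the zygosity cross-twin correlation.
#'
#' @param config a [simulation_config()].
#' @return A long-format data frame of observation rows (one rating of one
#'   child at one period by one rater) with attribute `seed`.
#' @export
#' @examples
#' cfg <- simulation_config(n_mz_pairs = 10, n_dz_pairs = 10, seed = 42)
#' head(simulate_twin_cohort(cfg))
simulate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- with_seed(config$seed, simulate_twin_cohort_impl(config))
  if (!is.null(config$missingness)) {
    rows <- apply_missingness(rows, config$missingness,
                              seed = substream_seed(config$seed, "missingness"))
  }
  if (config$cantril_discretize) rows$wellbeing <- discretize_cantril(rows$wellbeing)
  attr(rows, "seed") <- config$seed
  rows
}

simulate_twin_cohort_impl <- function(config) {
  cf <- config$cf_params
  periods <- cf$periods
  k <- length(periods)
  n_mz <- config$n_mz_pairs
  n_dz <- config$n_dz_pairs
  n <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))

  sa <- cf$sigma_a
  sc <- cf$sigma_c
  se <- cf$sigma_e
  if (!is.null(config$multirater)) {
    # rescale the common-phenotype variances to the per-period common
    # components while keeping the cross-period correlation structure
    for (comp in c("a", "c", "e")) {
      S <- get(paste0("s", comp))
      tgt <- vapply(periods, function(p) {
        config$multirater[[p]]$common[[paste0(comp, "2")]]
      }, numeric(1))
      d <- sqrt(tgt / pmax(diag(S), 1e-12))
      assign(paste0("s", comp), diag(d, k) %*% S %*% diag(d, k))
    }
  }

  draw_by_zyg <- function(sigma, rho_mz, rho_dz) {
    mz <- draw_twin_pair(n_mz, sigma, rho_mz)
    dz <- draw_twin_pair(n_dz, sigma, rho_dz)
    list(t1 = rbind(mz$t1, dz$t1), t2 = rbind(mz$t2, dz$t2))
  }
  A <- draw_by_zyg(sa, 1, 0.5)
  C <- draw_by_zyg(sc, 1, 1)
  E <- draw_by_zyg(se, 0, 0)
  common <- list(t1 = A$t1 + C$t1 + E$t1, t2 = A$t2 + C$t2 + E$t2)

  base_age <- runif(n, config$age_range[1], config$age_range[2])
  sex1 <- rbinom(n, 1, 0.5)
  sex2 <- ifelse(zyg == "MZ", sex1, rbinom(n, 1, 0.5))
  pea <- sample(names(config$pea_probs), n, replace = TRUE, prob = config$pea_probs)

  raters <- if (is.null(config$multirater)) "mother" else c("mother", "father")
  spec <- list()
  if (!is.null(config$multirater)) {
    for (r in raters) {
      sp <- matrix(0, n, 2 * k) # columns: twin1 periods, twin2 periods
      for (j in seq_len(k)) {
        prm <- config$multirater[[periods[j]]][[r]]
        a_r <- draw_by_zyg(matrix(prm$a2), 1, 0.5)
        c_r <- draw_by_zyg(matrix(prm$c2), 1, 1)
        e_r <- draw_by_zyg(matrix(prm$e2), 0, 0)
        sp[, j] <- a_r$t1 + c_r$t1 + e_r$t1
        sp[, k + j] <- a_r$t2 + c_r$t2 + e_r$t2
      }
      spec[[r]] <- sp
    }
  }

  fam_id <- sprintf("fam%06d", seq_len(n))
  out <- vector("list", 2 * k * length(raters))
  i <- 0L
  for (t in 1:2) {
    sex_t <- if (t == 1) sex1 else sex2
    com_t <- common[[paste0("t", t)]]
    for (j in seq_len(k)) {
      # 2 dp ages: generate from the emitted value for self-consistency
      age_j <- round(base_age + config$age_offset_years[j], 2)
      mu <- cf$intercepts[j] + cf$beta_age * age_j + cf$beta_sex * sex_t
      for (r in raters) {
        i <- i + 1L
        y <- mu + com_t[, j]
        if (!is.null(config$multirater)) {
          y <- y + spec[[r]][, if (t == 1) j else k + j]
        }
        out[[i]] <- data.frame(
          family_id = fam_id,
          individual_id = paste0(fam_id, "_", t),
          zygosity = zyg,
          wave = unname(config$wave_of_period[j]),
          period = periods[j],
          rater = r,
          sex = ifelse(sex_t == 1, "female", "male"),
          age = age_j,
          pea = pea,
          wellbeing = y,
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, out)
  rows <- rows[order(rows$family_id, rows$individual_id,
                     match(rows$period, periods), rows$rater), ]
  rownames(rows) <- NULL
  rows
}

#' Apply missing-completely-at-random observation and rater dropout
#'
#' Drops rows according to a [missingness_spec()]: child-level observation per
#' period (family-level for the baseline period, so twins share the
#' baseline-availability flag) and rater response per family x rater x period.
#' Deterministic given `seed`.
#'
#' @param rows long observation table.
#' @param missingness a [missingness_spec()].
#' @param seed integer seed.
#' @return The filtered observation table.
#' @export
apply_missingness <- function(rows, missingness, seed = 1L) {
  stopifnot(inherits(missingness, "missingness_spec"))
  with_seed(seed, {
    periods <- unique(rows$period)
    base_p <- periods[1]
    fams <- sort(unique(rows$family_id))
    inds <- unique(rows[, c("family_id", "individual_id")])
    inds <- inds[order(inds$family_id, inds$individual_id), ]
    keep <- rep(TRUE, nrow(rows))

    for (p in periods) {
      pr <- prob_for(missingness$obs_prob, p)
      in_p <- rows$period == p
      if (p == base_p) {
        ok <- setNames(rbinom(length(fams), 1, pr) == 1, fams)
        keep[in_p] <- keep[in_p] & ok[rows$family_id[in_p]]
      } else {
        ok <- setNames(rbinom(nrow(inds), 1, pr) == 1, inds$individual_id)
        keep[in_p] <- keep[in_p] & ok[rows$individual_id[in_p]]
      }
      for (r in sort(unique(rows$rater))) {
        rp <- prob_for(missingness$rater_prob, r)
        rp <- prob_for(rp, p)
        in_rp <- in_p & rows$rater == r
        okr <- setNames(rbinom(length(fams), 1, rp) == 1, fams)
        keep[in_rp] <- keep[in_rp] & okr[rows$family_id[in_rp]]
      }
    }
    out <- rows[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Round latent scores to the 0-10 Cantril ladder
#'
#' Rounds to the nearest integer (half-up) and clips to `[0, 10]`; monotone
#' non-decreasing in its input.
#'
#' @param latent_scores numeric vector.
#' @return Integer vector in 0..10.
#' @export
#' @examples
#' discretize_cantril(c(8.4, -1.2, 12.7)) # 8, 0, 10
discretize_cantril <- function(latent_scores) {
  as.integer(pmin(10, pmax(0, floor(latent_scores + 0.5))))
}

#' Cohort design for the mean-trend mixed model
#'
#' Describes the sampling frame a simulated cohort follows: a longitudinal
#' twin design (two children per family, observed at a baseline wave and
#' repeated pandemic waves with per-wave participation) or a cross-sectional
#' singleton design (each child sampled at exactly one wave).
#'
#' @param type `"twin"` or `"singleton"`.
#' @param n_families number of families (twin design) or children (singleton).
#' @param waves integer survey waves (0 = pre-pandemic baseline).
#' @param participation per-wave observation probability (twin design).
#' @param father_prob probability a row is father- rather than mother-rated.
#' @param age_range baseline age range in years.
#' @param pea_probs parental-educational-attainment proportions.
#' @return Object of class `lmm_design`.
#' @export
lmm_design <- function(type = c("twin", "singleton"), n_families, waves,
                       participation = 1, father_prob = 0.1,
                       age_range = c(7, 12),
                       pea_probs = c(low = 0.111, middle = 0.372, high = 0.517)) {
  type <- match.arg(type)
  structure(list(type = type, n_families = as.integer(n_families),
                 waves = as.integer(waves), participation = participation,
                 father_prob = father_prob, age_range = age_range,
                 pea_probs = pea_probs),
            class = "lmm_design")
}

#' @rdname lmm_design
#' @param n_families,n_children cohort size.
#' @export
lmm_design_ntr <- function(n_families = 10000) {
  lmm_design("twin", n_families, waves = 0:6,
             participation = c(`0` = 0.85, `1` = 0.4, `2` = 0.4, `3` = 0.4,
                               `4` = 0.4, `5` = 0.4, `6` = 0.4),
             father_prob = 0.10, age_range = c(7, 12),
             pea_probs = c(low = 0.111, middle = 0.372, high = 0.517))
}

#' @rdname lmm_design
#' @export
lmm_design_dreams <- function(n_children = 2500) {
  lmm_design("singleton", n_children, waves = 2:7, father_prob = 0.13,
             age_range = c(8, 18),
             pea_probs = c(low = 0.059, middle = 0.417, high = 0.524))
}

#' @rdname lmm_design
#' @export
lmm_design_klik <- function(n_children = 3100) {
  lmm_design("singleton", n_children, waves = 2:7, father_prob = 0.36,
             age_range = c(8, 18),
             pea_probs = c(low = 0.085, middle = 0.487, high = 0.428))
}

#' Simulate a cohort for the random-intercept mixed model
#'
#' Draws wellbeing scores from the mean model `Y = (b1 + u) + b2*wave +
#' b3*sex + b4*age + b5*PEA + b6*rater + e` with family and individual random
#' intercepts (twin design: individual nested within family; singleton
#' design: individual only) and independent residuals.
#'
#' @param spec an [lmm_spec()] of fixed effects and variance components.
#' @param design an [lmm_design()].
#' @param seed integer seed.
#' @return Long observation table with attribute `seed`.
#' @export
simulate_lmm_cohort <- function(spec, design, seed = 1L) {
  stopifnot(inherits(spec, "lmm_spec"), inherits(design, "lmm_design"))
  rows <- with_seed(seed, simulate_lmm_cohort_impl(spec, design))
  attr(rows, "seed") <- as.integer(seed)
  rows
}

simulate_lmm_cohort_impl <- function(spec, design) {
  nf <- design$n_families
  n_child <- if (design$type == "twin") 2L else 1L
  fam_id <- sprintf("fam%06d", seq_len(nf))
  b_fam <- rnorm(nf, 0, sqrt(spec$var_family))
  base_age <- runif(nf, design$age_range[1], design$age_range[2])
  pea <- sample(names(design$pea_probs), nf, replace = TRUE, prob = design$pea_probs)
  zyg <- if (design$type == "twin") {
    sample(c("MZ", "DZ"), nf, replace = TRUE)
  } else {
    rep("none", nf)
  }

  out <- list()
  for (t in seq_len(n_child)) {
    ind_id <- paste0(fam_id, "_", t)
    b_ind <- rnorm(nf, 0, sqrt(spec$var_individual))
    sexf <- rbinom(nf, 1, 0.5)
    if (design$type == "singleton") {
      w <- sample(design$waves, nf, replace = TRUE)
      obs <- data.frame(fam = seq_len(nf), wave = w)
    } else {
      obs <- do.call(rbind, lapply(design$waves, function(w) {
        pr <- prob_for(design$participation, as.character(w))
        sel <- which(rbinom(nf, 1, pr) == 1)
        if (!length(sel)) return(NULL)
        data.frame(fam = sel, wave = w)
      }))
    }
    f <- obs$fam
    wv <- obs$wave
    wave_off <- ifelse(as.character(wv) %in% names(spec$wave),
                       spec$wave[as.character(wv)], 0)
    # ages are emitted at 2 dp; generate from the emitted value so the
    # output table is exactly self-consistent
    age <- round(base_age[f] + 0.5 * (wv - min(design$waves)), 2)
    father <- rbinom(nrow(obs), 1, design$father_prob)
    y <- spec$intercept + wave_off + spec$sex_female * sexf[f] +
      spec$age * age +
      spec$pea_low * (pea[f] == "low") + spec$pea_middle * (pea[f] == "middle") +
      spec$rater_father * father +
      b_fam[f] + b_ind[f] + rnorm(nrow(obs), 0, sqrt(spec$var_residual))
    out[[t]] <- data.frame(
      family_id = fam_id[f], individual_id = ind_id[f], zygosity = zyg[f],
      wave = wv, period = wave_to_period(wv),
      rater = ifelse(father == 1, "father", "mother"),
      sex = ifelse(sexf[f] == 1, "female", "male"),
      age = age, pea = pea[f], wellbeing = y,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, out)
  rows <- rows[order(rows$family_id, rows$individual_id, rows$wave), ]
  rownames(rows) <- NULL
  rows
}
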