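# Psychometric multi-rater twin model. Each parent's rating is the sum of a
# common latent child phenotype (rater agreement) and a rater-specific part
# (disagreement), each ACE-decomposed. Rater-specific C is the rater-bias
# component: shared across both twins within a rater. Also provides the
# constrained saturated covariance model used to test the identifying
# equality constraints.

#' Expected covariance of the psychometric multi-rater model
#'
#' Variable order is (mother-rating twin 1, father-rating twin 1,
#' mother-rating twin 2, father-rating twin 2). With common components
#' `A, C, E` and rater-specific components `A_r, C_r, E_r`:
#' `var(r_j) = (A+C+E) + (A_r+C_r+E_r)`; same-twin cross-rater covariance
#' `= A+C+E` (identical for MZ and DZ by construction); cross-twin same-rater
#' covariance `= k*A + C + k*A_r + C_r` (the bias component `C_r` is fully
#' shared across twins); cross-twin cross-rater covariance `= k*A + C`;
#' `k = 1` (MZ) or `0.5` (DZ).
#'
#' @param params a [multirater_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 4 x 4 covariance matrix over (m1, f1, m2, f2).
#' @export
build_multirater_expected_cov <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "multirater_params"))
  zygosity <- match.arg(zygosity)
  k <- if (zygosity == "MZ") 1 else 0.5
  cm <- params$common
  mo <- params$mother
  fa <- params$father
  ctot <- cm$a2 + cm$c2 + cm$e2
  vm <- ctot + mo$a2 + mo$c2 + mo$e2
  vf <- ctot + fa$a2 + fa$c2 + fa$e2
  ctcr <- k * cm$a2 + cm$c2
  mm <- ctcr + k * mo$a2 + mo$c2
  ff <- ctcr + k * fa$a2 + fa$c2
  S <- matrix(c(vm, ctot, mm, ctcr,
                ctot, vf, ctcr, ff,
                mm, ctcr, vm, ctot,
                ctcr, ff, ctot, vf), 4, 4)
  dimnames(S) <- list(c("m1", "f1", "m2", "f2"), c("m1", "f1", "m2", "f2"))
  S
}

# Reshape one period of long observations into family x (m1, f1, m2, f2).
mr_prepare <- function(data, period) {
  d <- data[data$period == period & data$zygosity %in% c("MZ", "DZ") &
              data$rater %in% c("mother", "father"), , drop = FALSE]
  if (nrow(d) == 0) stop("no usable observations for period '", period, "'")
  d <- d[order(d$individual_id, d$rater, d$wave), ]
  d <- d[!duplicated(paste(d$individual_id, d$rater)), , drop = FALSE]

  ind <- unique(d[, c("family_id", "individual_id", "sex")])
  ind <- ind[order(ind$family_id, ind$individual_id), ]
  iord <- stats::ave(seq_len(nrow(ind)), ind$family_id, FUN = seq_along)
  ind <- ind[iord <= 2, , drop = FALSE]
  iord <- iord[iord <= 2]
  fams <- unique(d[, c("family_id", "zygosity")])
  fams <- fams[order(fams$family_id), ]
  n <- nrow(fams)

  Y <- Age <- matrix(NA_real_, n, 4,
                     dimnames = list(NULL, c("m1", "f1", "m2", "f2")))
  SexF <- matrix(0, n, 4)
  twin_of <- setNames(iord, ind$individual_id)
  d <- d[d$individual_id %in% names(twin_of), , drop = FALSE]
  ri <- match(d$family_id, fams$family_id)
  ci <- (twin_of[d$individual_id] - 1) * 2 + match(d$rater, c("mother", "father"))
  Y[cbind(ri, ci)] <- d$wellbeing
  Age[cbind(ri, ci)] <- d$age
  SexF[cbind(ri, ci)] <- as.numeric(d$sex == "female")
  keep <- rowSums(!is.na(Y)) > 0
  list(Y = Y[keep, , drop = FALSE], Age = Age[keep, , drop = FALSE],
       SexF = SexF[keep, , drop = FALSE], zygosity = fams$zygosity[keep],
       family_id = fams$family_id[keep])
}

# Sample covariance summaries per zygosity used for starting values.
mr_moments <- function(prep) {
  stat <- function(z) {
    S <- cov(prep$Y[prep$zygosity == z, , drop = FALSE],
             use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    S
  }
  smz <- stat("MZ")
  sdz <- stat("DZ")
  list(
    vm = mean(c(smz[1, 1], smz[3, 3], sdz[1, 1], sdz[3, 3])),
    vf = mean(c(smz[2, 2], smz[4, 4], sdz[2, 2], sdz[4, 4])),
    stc = mean(c(smz[1, 2], smz[3, 4], sdz[1, 2], sdz[3, 4])),
    mm = c(MZ = smz[1, 3], DZ = sdz[1, 3]),
    ff = c(MZ = smz[2, 4], DZ = sdz[2, 4]),
    ctcr = c(MZ = mean(c(smz[1, 4], smz[2, 3])),
             DZ = mean(c(sdz[1, 4], sdz[2, 3]))))
}

mr_mean_matrix <- function(par, prep) {
  Age0 <- prep$Age
  Age0[is.na(Age0)] <- 0
  mu_r <- par[c(1, 2, 1, 2)] # mother, father intercepts
  matrix(mu_r, nrow(prep$Y), 4, byrow = TRUE) + par[3] * Age0 + par[4] * prep$SexF
}

#' Fit the psychometric multi-rater model for one period
#'
#' Maximum-likelihood estimation of the nine variance components (common A,
#' C, E plus mother- and father-specific A, C, E) and the mean model
#' (rater intercepts, age, sex) from mother and father ratings of both
#' twins. Families with only one responding rater contribute through the
#' raw-data likelihood. Components are parameterized on the
#' standard-deviation scale, so all reported components are non-negative.
#'
#' @param data long observation table.
#' @param period period label to fit.
#' @param n_restarts jittered optimizer restarts.
#' @param se compute observed-information standard errors.
#' @return Object of class `psychometric_fit`: `params` (fitted
#'   [multirater_params()]), `fit` (a `twin_fit`), `views`
#'   ([decompose_views()] of the fitted components), `n_families`.
#' @export
fit_psychometric <- function(data, period, n_restarts = 5, se = FALSE) {
  prep <- mr_prepare(data, period)
  both <- rowSums(!is.na(prep$Y[, c(1, 2)])) == 2 |
    rowSums(!is.na(prep$Y[, c(3, 4)])) == 2
  if (!any(both)) {
    stop("no family has both raters observed for the same twin; ",
         "common and specific components are not separable")
  }
  pat <- fiml_patterns(prep$Y, as.integer(factor(prep$zygosity, c("MZ", "DZ"))))

  mk_params <- function(u) {
    v <- u^2
    multirater_params(common = ace_params(v[1], v[2], max(v[3], 1e-8)),
                      mother = ace_params(v[4], v[5], max(v[6], 1e-8)),
                      father = ace_params(v[7], v[8], max(v[9], 1e-8)))
  }
  neg2ll <- function(par) {
    prm <- mk_params(par[5:13])
    sig <- list(build_multirater_expected_cov(prm, "MZ"),
                build_multirater_expected_cov(prm, "DZ"))
    -2 * fiml_loglik_resid(prep$Y - mr_mean_matrix(par, prep), sig, pat)
  }

  mo <- mr_moments(prep)
  A0 <- 2 * (mo$ctcr["MZ"] - mo$ctcr["DZ"])
  C0 <- 2 * mo$ctcr["DZ"] - mo$ctcr["MZ"]
  E0 <- mo$stc - A0 - C0
  Am0 <- 2 * (mo$mm["MZ"] - mo$mm["DZ"]) - A0
  Cm0 <- (2 * mo$mm["DZ"] - mo$mm["MZ"]) - C0
  Em0 <- mo$vm - mo$stc - Am0 - Cm0
  Af0 <- 2 * (mo$ff["MZ"] - mo$ff["DZ"]) - A0
  Cf0 <- (2 * mo$ff["DZ"] - mo$ff["MZ"]) - C0
  Ef0 <- mo$vf - mo$stc - Af0 - Cf0
  v0 <- pmax(c(A0, C0, E0, Am0, Cm0, Em0, Af0, Cf0, Ef0), 0.01)
  mu_m0 <- mean(prep$Y[, c(1, 3)], na.rm = TRUE)
  mu_f0 <- mean(prep$Y[, c(2, 4)], na.rm = TRUE)
  if (!is.finite(mu_f0)) mu_f0 <- mu_m0
  par0 <- c(mu_m0, mu_f0, 0, 0, sqrt(v0))

  opt <- ml_fit(neg2ll, par0, n_restarts = n_restarts,
                restart_seed = substream_seed(13L, paste0("psy-", period)))
  comp_names <- c("A", "C", "E", "A_m", "C_m", "E_m", "A_f", "C_f", "E_f")
  est <- c(setNames(opt$par[1:4], c("mu_mother", "mu_father", "beta_age", "beta_sex")),
           setNames(opt$par[5:13]^2, comp_names))
  params <- mk_params(opt$par[5:13])

  pm <- c(setNames(lapply(1:4, function(i) list(index = i, trans = "id")),
                   c("mu_mother", "mu_father", "beta_age", "beta_sex")),
          setNames(lapply(1:9, function(i) list(index = i + 4L, trans = "sq")),
                   comp_names))
  se_v <- NULL
  if (se) {
    H <- num_hessian(neg2ll, opt$par)
    cv <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      sd_int <- sqrt(pmax(diag(cv), 0))
      se_v <- setNames(c(sd_int[1:4], abs(2 * opt$par[5:13]) * sd_int[5:13]),
                       names(est))
    }
  }
  fit <- new_twin_fit(model = paste0("psychometric multi-rater (", period, ")"),
                      estimates = est, minus2ll = opt$objective,
                      converged = opt$converged, n_obs = nrow(prep$Y),
                      n_par = length(par0), se = se_v, par = opt$par,
                      neg2ll = neg2ll, profile_map = pm)
  structure(list(params = params, fit = fit, views = decompose_views(params),
                 n_families = nrow(prep$Y), period = period),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric multi-rater fit, period:", x$period,
      sprintf("(%d families)\n", x$n_families))
  print(x$params)
  cat(sprintf("common-view share of two-rater total: %.1f%%\n",
              100 * x$views$combined_common_share))
  invisible(x)
}

# Covariance matrices of the constrained / order-symmetric saturated models.
mr_sat_cov <- function(v, constrained) {
  # v layout (constrained): vm, vf, stc, mm_MZ, ff_MZS, ctcr_MZ, mm_DZ, ff_DZ, ctcr_DZ
  # v layout (free): vm, vf, stc_MZ, stc_DZ, mm_MZ, ff_MZ, c12_MZ, c21_MZ,
  #                  mm_DZ, ff_DZ, c12_DZ, c21_DZ
  mk <- function(vm, vf, stc, mm, ff, c12, c21) {
    matrix(c(vm, stc, mm, c12,
             stc, vf, c21, ff,
             mm, c21, vm, stc,
             c12, ff, stc, vf), 4, 4)
  }
  if (constrained) {
    list(mk(v[1], v[2], v[3], v[4], v[5], v[6], v[6]),
         mk(v[1], v[2], v[3], v[7], v[8], v[9], v[9]))
  } else {
    list(mk(v[1], v[2], v[3], v[5], v[6], v[7], v[8]),
         mk(v[1], v[2], v[4], v[9], v[10], v[11], v[12]))
  }
}

#' Fit the constrained saturated covariance model for one period
#'
#' Fits, per zygosity, a 4 x 4 covariance matrix over (m1, f1, m2, f2) with
#' means adjusted for rater, age and sex, under the two identifying equality
#' constraints of the multi-rater design: (1) the same-twin cross-rater
#' covariance is equal across zygosities and (2) the cross-twin cross-rater
#' covariance is equal across twin order. The comparison ("free") model
#' releases exactly those constraints (both models share rating variances
#' across twin order, which is arbitrary). A likelihood-ratio test reports
#' whether the constraints are tenable; the constrained (more parsimonious)
#' model is retained when the test is non-significant at `alpha`.
#'
#' @param data long observation table.
#' @param period period label to fit.
#' @param alpha significance level of the constraint test.
#' @param n_restarts jittered optimizer restarts.
#' @return List with the constrained and free `twin_fit`s, the per-zygosity
#'   fitted matrices, the `lrt` result, `constraints_satisfied`, and the
#'   same-twin cross-rater correlation implied by the constrained model.
#' @export
fit_constrained_saturated <- function(data, period, alpha = 0.05, n_restarts = 3) {
  prep <- mr_prepare(data, period)
  both <- rowSums(!is.na(prep$Y[, c(1, 2)])) == 2 |
    rowSums(!is.na(prep$Y[, c(3, 4)])) == 2
  if (!any(both)) {
    stop("no family has both raters observed for the same twin; ",
         "cross-rater covariances are not identified")
  }
  pat <- fiml_patterns(prep$Y, as.integer(factor(prep$zygosity, c("MZ", "DZ"))))
  fit_one <- function(constrained) {
    nv <- if (constrained) 9L else 12L
    neg2ll <- function(par) {
      sig <- mr_sat_cov(par[4 + 1:nv], constrained)
      -2 * fiml_loglik_resid(prep$Y - mr_mean_matrix(par, prep), sig, pat)
    }
    mo <- mr_moments(prep)
    v0 <- if (constrained) {
      c(mo$vm, mo$vf, mo$stc, mo$mm["MZ"], mo$ff["MZ"], mo$ctcr["MZ"],
        mo$mm["DZ"], mo$ff["DZ"], mo$ctcr["DZ"])
    } else {
      c(mo$vm, mo$vf, mo$stc, mo$stc, mo$mm["MZ"], mo$ff["MZ"],
        mo$ctcr["MZ"], mo$ctcr["MZ"], mo$mm["DZ"], mo$ff["DZ"],
        mo$ctcr["DZ"], mo$ctcr["DZ"])
    }
    mu_m0 <- mean(prep$Y[, c(1, 3)], na.rm = TRUE)
    mu_f0 <- mean(prep$Y[, c(2, 4)], na.rm = TRUE)
    if (!is.finite(mu_f0)) mu_f0 <- mu_m0
    par0 <- c(mu_m0, mu_f0, 0, 0, v0)
    lower <- c(rep(-Inf, 4), 1e-6, 1e-6, rep(-Inf, nv - 2))
    opt <- ml_fit(neg2ll, par0, n_restarts = n_restarts, lower = lower,
                  restart_seed = substream_seed(17L, paste0("sat-", period, constrained)))
    nm <- if (constrained) {
      c("var_m", "var_f", "stc", "mm_MZ", "ff_MZ", "ctcr_MZ",
        "mm_DZ", "ff_DZ", "ctcr_DZ")
    } else {
      c("var_m", "var_f", "stc_MZ", "stc_DZ", "mm_MZ", "ff_MZ", "c12_MZ",
        "c21_MZ", "mm_DZ", "ff_DZ", "c12_DZ", "c21_DZ")
    }
    est <- c(setNames(opt$par[1:4], c("mu_mother", "mu_father", "beta_age", "beta_sex")),
             setNames(opt$par[4 + 1:nv], nm))
    new_twin_fit(model = paste0(if (constrained) "constrained" else "free",
                                " saturated (", period, ")"),
                 estimates = est, minus2ll = opt$objective,
                 converged = opt$converged, n_obs = nrow(prep$Y),
                 n_par = length(par0), par = opt$par, neg2ll = neg2ll)
  }
  con <- fit_one(TRUE)
  fre <- fit_one(FALSE)
  test <- lrt(fre, con)
  v <- con$estimates
  sig <- mr_sat_cov(unname(v[5:13]), TRUE)
  names(sig) <- c("MZ", "DZ")
  list(constrained = con, free = fre, lrt = test,
       constraints_satisfied = test$p > alpha,
       matrices = sig,
       cross_rater_correlation =
         unname(v["stc"] / sqrt(v["var_m"] * v["var_f"])),
       n_families = con$n_obs)
}

#' Decompose rater variance into common-view and rater-specific shares
#'
#' For each rater, the common-view share is the fraction of that rater's
#' rating variance carried by the latent phenotype both raters observe; the
#' remainder is rater-specific, with its own A/C/E shares. The
#' rater-specific C share is the rater-bias index: a systematic rating
#' tendency shared across both twins by one rater. The combined common-view
#' share uses the two-rater total (common counted once plus both raters'
#' specific parts) as denominator, the decomposition of total phenotypic
#' variance across both views.
#'
#' @param params a [multirater_params()] object or a `psychometric_fit`.
#' @return Object of class `view_decomposition`: per-rater lists (`total`,
#'   `common_share`, `specific_share`, `bias_share`, and the six A/C/E
#'   shares of the rater's total) plus `combined_common_share`.
#' @export
decompose_views <- function(params) {
  if (inherits(params, "psychometric_fit")) params <- params$params
  stopifnot(inherits(params, "multirater_params"))
  ctot <- total_variance(params$common)
  one <- function(spec) {
    stot <- total_variance(spec)
    tot <- ctot + stot
    if (tot <= 0) stop("zero total rating variance: shares undefined")
    list(total = tot,
         common_share = ctot / tot,
         specific_share = stot / tot,
         bias_share = spec$c2 / tot,
         shares = c(common_a = params$common$a2, common_c = params$common$c2,
                    common_e = params$common$e2, specific_a = spec$a2,
                    specific_c = spec$c2, specific_e = spec$e2) / tot)
  }
  sm <- total_variance(params$mother)
  sf <- total_variance(params$father)
  structure(list(mother = one(params$mother), father = one(params$father),
                 combined_common_share = ctot / (ctot + sm + sf)),
            class = "view_decomposition")
}

#' @export
print.view_decomposition <- function(x, ...) {
  cat("View decomposition (shares of each rater's total variance)\n")
  for (r in c("mother", "father")) {
    v <- x[[r]]
    cat(sprintf("  %-6s common %.1f%% | specific %.1f%% (bias C_r %.1f%%)\n",
                r, 100 * v$common_share, 100 * v$specific_share,
                100 * v$bias_share))
  }
  cat(sprintf("  combined common-view share of two-rater total: %.1f%%\n",
              100 * x$combined_common_share))
  invisible(x)
}
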