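# Four-period correlated factors ACE model: expected covariance construction,
# raw-data ML fitting, and the derived quantities (component correlations,
# standardized variance and covariance shares, report tables).

#' Expected twin-pair covariance of the correlated factors model
#'
#' The within-twin block over periods is `SigmaA + SigmaC + SigmaE`; the
#' cross-twin block is `k * SigmaA + SigmaC` with `k = 1` (MZ) or `0.5` (DZ).
#'
#' @param params a [cf_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A `2k x 2k` covariance matrix (twin 1 periods, then twin 2).
#' @export
build_cf_expected_cov <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "cf_params"))
  zygosity <- match.arg(zygosity)
  k_a <- if (zygosity == "MZ") 1 else 0.5
  P <- phenotypic_cov(params)
  CT <- k_a * params$sigma_a + params$sigma_c
  rbind(cbind(P, CT), cbind(t(CT), P))
}

# Reshape long observations for the single-rater multivariate twin fit:
# mother's rating preferred when both parents rated; earliest wave within a
# collapsed period; twin order by individual id.
cf_prepare <- function(data, periods = default_periods()) {
  d <- data[data$zygosity %in% c("MZ", "DZ") &
              data$rater %in% c("mother", "father") &
              data$period %in% periods, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable twin observations in data")
  d <- d[order(d$individual_id, d$period,
               match(d$rater, c("mother", "father")), d$wave), ]
  d <- d[!duplicated(paste(d$individual_id, d$period)), , drop = FALSE]

  ind <- unique(d[, c("family_id", "individual_id", "sex", "zygosity")])
  ind <- ind[order(ind$family_id, ind$individual_id), ]
  iord <- stats::ave(seq_len(nrow(ind)), ind$family_id, FUN = seq_along)
  ind <- ind[iord <= 2, , drop = FALSE]
  iord <- iord[iord <= 2]
  fams <- unique(ind[, c("family_id", "zygosity")])
  n <- nrow(fams)
  k <- length(periods)

  Y <- Age <- matrix(NA_real_, n, 2 * k)
  SexF <- matrix(0, n, 2 * k)
  twin_of <- setNames(iord, ind$individual_id)
  d <- d[d$individual_id %in% names(twin_of), , drop = FALSE]
  ri <- match(d$family_id, fams$family_id)
  ci <- (twin_of[d$individual_id] - 1) * k + match(d$period, periods)
  Y[cbind(ri, ci)] <- d$wellbeing
  Age[cbind(ri, ci)] <- d$age
  SexF[cbind(ri, ci)] <- as.numeric(d$sex == "female")

  keep <- rowSums(!is.na(Y)) > 0
  list(Y = Y[keep, , drop = FALSE], Age = Age[keep, , drop = FALSE],
       SexF = SexF[keep, , drop = FALSE],
       zygosity = fams$zygosity[keep], family_id = fams$family_id[keep],
       periods = periods, k = k)
}

# Moment-based (Falconer-style) starting matrices from sample covariances.
cf_start_matrices <- function(prep) {
  k <- prep$k
  Y <- prep$Y
  both <- rbind(Y[, 1:k, drop = FALSE], Y[, k + 1:k, drop = FALSE])
  P0 <- cov(both, use = "pairwise.complete.obs")
  P0[is.na(P0)] <- 0
  cross <- function(z) {
    w <- prep$zygosity == z
    M <- cov(Y[w, 1:k, drop = FALSE], Y[w, k + 1:k, drop = FALSE],
             use = "pairwise.complete.obs")
    M[is.na(M)] <- 0
    (M + t(M)) / 2
  }
  ct_mz <- cross("MZ")
  ct_dz <- cross("DZ")
  A0 <- 2 * (ct_mz - ct_dz)
  C0 <- 2 * ct_dz - ct_mz
  E0 <- P0 - A0 - C0
  list(A = A0, C = C0, E = E0, P = P0)
}

#' Fit the correlated factors ACE model by raw-data maximum likelihood
#'
#' Fits the multivariate twin model in which each period has its own A, C and
#' E factors correlating across periods. All missing-data patterns contribute
#' through the raw-data likelihood (no listwise deletion). The three
#' component matrices are parameterized by unconstrained matrix square roots
#' (`Sigma = L L'`), so every fitted component matrix is positive
#' semi-definite; the mean model has a free intercept per period plus linear
#' age and sex effects shared across periods and zygosities. Starting values
#' are Falconer-style moment estimates; optimization uses quasi-Newton search
#' with jittered restarts.
#'
#' @param data long observation table (one parent's rating per child per
#'   period is selected internally: mother preferred, earliest wave within a
#'   period).
#' @param periods period labels, in order.
#' @param n_restarts jittered optimizer restarts.
#' @param se compute observed-information standard errors of the reported
#'   variance/covariance entries (adds a Hessian evaluation; off by default
#'   for this 36-parameter model).
#' @return An object of class `cf_fit`: `params` (fitted [cf_params()]),
#'   `fit` (a `twin_fit`), `n_families`, and `unidentified` (periods with no
#'   complete cross-twin pairs in some zygosity, where the A/C split is not
#'   identified).
#' @export
fit_correlated_factors <- function(data, periods = default_periods(),
                                   n_restarts = 3, se = FALSE) {
  prep <- cf_prepare(data, periods)
  k <- prep$k
  nl <- k * (k + 1) / 2
  pat <- fiml_patterns(prep$Y, as.integer(factor(prep$zygosity, c("MZ", "DZ"))))

  col_period <- rep(seq_len(k), 2)
  Age0 <- prep$Age
  Age0[is.na(Age0)] <- 0

  neg2ll <- function(par) {
    La <- ltri_to_mat(par[1:nl], k)
    Lc <- ltri_to_mat(par[nl + 1:nl], k)
    Le <- ltri_to_mat(par[2 * nl + 1:nl], k)
    SA <- tcrossprod(La)
    SC <- tcrossprod(Lc)
    SE <- tcrossprod(Le)
    P <- SA + SC + SE
    sig <- list(rbind(cbind(P, SA + SC), cbind(SA + SC, P)),
                rbind(cbind(P, 0.5 * SA + SC), cbind(0.5 * SA + SC, P)))
    ic <- par[3 * nl + 1:k]
    ba <- par[3 * nl + k + 1]
    bs <- par[3 * nl + k + 2]
    Mu <- matrix(ic[col_period], nrow(prep$Y), 2 * k, byrow = TRUE) +
      ba * Age0 + bs * prep$SexF
    -2 * fiml_loglik_resid(prep$Y - Mu, sig, pat)
  }

  st <- cf_start_matrices(prep)
  mean_age <- mean(prep$Age, na.rm = TRUE)
  ic0 <- vapply(seq_len(k), function(j) {
    mean(c(prep$Y[, j], prep$Y[, k + j]), na.rm = TRUE)
  }, numeric(1))
  par0 <- c(mat_to_ltri(psd_chol_start(st$A, 0.02)),
            mat_to_ltri(psd_chol_start(st$C, 0.02)),
            mat_to_ltri(psd_chol_start(st$E, 0.02)),
            ic0, 0, 0)
  opt <- ml_fit(neg2ll, par0, n_restarts = n_restarts, jitter = 0.15,
                restart_seed = substream_seed(11L, "cf"))

  La <- ltri_to_mat(opt$par[1:nl], k)
  Lc <- ltri_to_mat(opt$par[nl + 1:nl], k)
  Le <- ltri_to_mat(opt$par[2 * nl + 1:nl], k)
  fitted <- cf_params(tcrossprod(La), tcrossprod(Lc), tcrossprod(Le),
                      periods = periods,
                      intercepts = opt$par[3 * nl + 1:k],
                      beta_age = opt$par[3 * nl + k + 1],
                      beta_sex = opt$par[3 * nl + k + 2])

  est <- c(cf_named_entries(fitted),
           setNames(fitted$intercepts, paste0("mu[", periods, "]")),
           beta_age = fitted$beta_age, beta_sex = fitted$beta_sex)

  unident <- vapply(seq_len(k), function(j) {
    cc <- complete.cases(prep$Y[, c(j, k + j)])
    any(vapply(c("MZ", "DZ"), function(z) sum(cc & prep$zygosity == z) == 0,
               logical(1)))
  }, logical(1))

  fit <- new_twin_fit(model = "correlated factors ACE",
                      estimates = est, minus2ll = opt$objective,
                      converged = opt$converged, n_obs = nrow(prep$Y),
                      n_par = length(par0), par = opt$par, neg2ll = neg2ll)
  if (se) {
    H <- num_hessian(neg2ll, opt$par)
    fit$vcov_internal <- tryCatch(2 * solve(H), error = function(e) NULL)
  }
  structure(list(params = fitted, fit = fit, n_families = nrow(prep$Y),
                 unidentified = periods[unident], periods = periods),
            class = "cf_fit")
}

cf_named_entries <- function(params) {
  k <- length(params$periods)
  out <- c()
  for (comp in c("A", "C", "E")) {
    S <- params[[paste0("sigma_", tolower(comp))]]
    for (i in seq_len(k)) for (j in seq_len(i)) {
      out[sprintf("%s[%s,%s]", comp, params$periods[j], params$periods[i])] <- S[j, i]
    }
  }
  out
}

#' @export
print.cf_fit <- function(x, digits = 3, ...) {
  cat("Correlated factors ACE fit over", length(x$periods), "periods,",
      x$n_families, "families\n")
  cat(sprintf("-2lnL = %.3f, converged: %s\n", x$fit$minus2ll, x$fit$converged))
  if (length(x$unidentified)) {
    cat("A/C split not identified for period(s):",
        paste(x$unidentified, collapse = ", "), "\n")
  }
  print(x$params, digits = digits)
  invisible(x)
}

#' Correlation between component factors of two periods
#'
#' `r = cov / sqrt(var_i * var_j)` — used both for genetic/environmental
#' correlations from component matrices and for phenotypic correlations from
#' phenotypic (co)variances.
#'
#' @param cov_ij component covariance between periods i and j.
#' @param var_i,var_j component variances.
#' @return The correlation (vectorized).
#' @export
#' @examples
#' correlation_from_components(0.21, 0.38, 0.39) # genetic correlation 0.55
correlation_from_components <- function(cov_ij, var_i, var_j) {
  ifelse(var_i > 0 & var_j > 0, cov_ij / sqrt(var_i * var_j), NA_real_)
}

safe_cov2cor <- function(S) {
  d <- diag(S)
  R <- outer(seq_along(d), seq_along(d),
             Vectorize(function(i, j) correlation_from_components(S[i, j], d[i], d[j])))
  dimnames(R) <- dimnames(S)
  R
}

#' Component correlation matrices of a correlated factors model
#'
#' Genetic (`rA`), shared-environment (`rC`), non-shared environment (`rE`)
#' and phenotypic (`rP`) correlation matrices across periods. A genetic
#' correlation below 1 between two periods indicates partially different
#' genes at work (gene-environment interaction). Entries involving a
#' zero-variance component are undefined and returned as `NA`.
#'
#' @param params a [cf_params()] object or a `cf_fit`.
#' @return Object of class `cf_derived` with matrices `rA`, `rC`, `rE`, `rP`.
#' @export
component_correlations <- function(params) {
  if (inherits(params, "cf_fit")) params <- params$params
  stopifnot(inherits(params, "cf_params"))
  structure(list(rA = safe_cov2cor(params$sigma_a),
                 rC = safe_cov2cor(params$sigma_c),
                 rE = safe_cov2cor(params$sigma_e),
                 rP = safe_cov2cor(phenotypic_cov(params))),
            class = "cf_derived")
}

#' Standardized variance and covariance shares of the A/C/E components
#'
#' Diagonal entries give each component's share of the phenotypic variance of
#' a period; off-diagonal entries give each component's share of the
#' phenotypic covariance between two periods ("what fraction of the stability
#' of wellbeing between two periods is genetic / shared-environmental?").
#' Standardization uses the model-implied phenotypic matrix (the elementwise
#' sum of the components), so shares sum to 1 per cell by construction.
#' Cells with zero phenotypic (co)variance are undefined (`NA`).
#'
#' @param params a [cf_params()] object or a `cf_fit`.
#' @return Object of class `cf_derived` with matrices `A`, `C`, `E`.
#' @export
standardize_components <- function(params) {
  if (inherits(params, "cf_fit")) params <- params$params
  stopifnot(inherits(params, "cf_params"))
  P <- phenotypic_cov(params)
  share <- function(S) {
    out <- ifelse(abs(P) > 1e-12, S / P, NA_real_)
    dimnames(out) <- dimnames(S)
    out
  }
  structure(list(A = share(params$sigma_a), C = share(params$sigma_c),
                 E = share(params$sigma_e)),
            class = "cf_derived")
}

#' Report tables for a correlated factors fit
#'
#' Emits the unstandardized table (phenotypic and A/C/E variances and
#' covariances in the lower triangle plus the corresponding correlations) and
#' the standardized table (variance shares on the diagonal, covariance shares
#' off it), rounded to 2 decimal places on output.
#'
#' @param x a `cf_fit` or [cf_params()] object.
#' @param digits rounding for the emitted tables.
#' @return List with data frames `unstandardized` and `standardized`.
#' @export
reproduce_tables <- function(x, digits = 2) {
  params <- if (inherits(x, "cf_fit")) x$params else x
  stopifnot(inherits(params, "cf_params"))
  periods <- params$periods
  k <- length(periods)
  comps <- list(phenotypic = phenotypic_cov(params), A = params$sigma_a,
                C = params$sigma_c, E = params$sigma_e)
  unstd <- do.call(rbind, lapply(names(comps), function(nm) {
    S <- comps[[nm]]
    R <- safe_cov2cor(S)
    do.call(rbind, lapply(seq_len(k), function(i) {
      do.call(rbind, lapply(seq_len(i), function(j) {
        data.frame(component = nm, period_i = periods[i], period_j = periods[j],
                   estimate = round(S[i, j], digits),
                   correlation = if (i == j) NA_real_ else round(R[i, j], digits),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  shares <- standardize_components(params)
  std <- do.call(rbind, lapply(c("A", "C", "E"), function(nm) {
    S <- shares[[nm]]
    do.call(rbind, lapply(seq_len(k), function(i) {
      do.call(rbind, lapply(seq_len(i), function(j) {
        data.frame(component = nm, period_i = periods[i], period_j = periods[j],
                   share = round(S[i, j], digits), stringsAsFactors = FALSE)
      }))
    }))
  }))
  list(unstandardized = unstd, standardized = std)
}
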