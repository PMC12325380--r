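# Random-intercept linear mixed model of mean wellbeing per wave, fit by
# maximum likelihood with a closed-form marginal covariance per family:
# same observation:            var_family + var_individual + var_residual
# same individual, other obs:  var_family + var_individual
# same family, other individual: var_family
# The likelihood is evaluated with two nested Woodbury identities (collapse
# over individuals, then over families), so each evaluation is a handful of
# grouped sums -- no per-family matrix inversion.

lmm_design_matrix <- function(rows, reference_wave, covariates,
                              wave_levels = sort(unique(rows$wave)),
                              check = TRUE) {
  n <- nrow(rows)
  cols <- list(`(Intercept)` = rep(1, n))
  if ("wave" %in% covariates) {
    for (w in setdiff(wave_levels, reference_wave)) {
      cols[[paste0("wave", w)]] <- as.numeric(rows$wave == w)
    }
  }
  if ("sex" %in% covariates) cols$sexfemale <- as.numeric(rows$sex == "female")
  if ("age" %in% covariates) cols$age <- rows$age
  if ("pea" %in% covariates) {
    cols$pealow <- as.numeric(rows$pea == "low")
    cols$peamiddle <- as.numeric(rows$pea == "middle")
  }
  if ("rater" %in% covariates) cols$raterfather <- as.numeric(rows$rater == "father")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (check) {
    const <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
    if (any(const)) {
      message("dropping constant term(s): ",
              paste(names(const)[const], collapse = ", "))
      X <- X[, c(TRUE, !const), drop = FALSE]
    }
    q <- qr(X)
    if (q$rank < ncol(X)) {
      aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
      stop("design matrix is rank deficient; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
  }
  X
}

# Marginal -2 log-likelihood and GLS quantities at given variance components.
lmm_eval <- function(pre, s2f, s2i, s2e) {
  d_j <- s2e + pre$n_j * s2i
  w_j <- s2i / d_j
  ytDy <- (pre$sum_y2 - sum(w_j * pre$SyI^2)) / s2e
  XtDX <- (pre$XtX - crossprod(pre$SXI * sqrt(w_j))) / s2e
  XtDy <- (pre$Xty - crossprod(pre$SXI, pre$SyI * w_j)) / s2e
  u_f <- rowsum(pre$SXI / d_j, pre$fam_of_ind)
  v_f <- rowsum(pre$SyI / d_j, pre$fam_of_ind)[, 1]
  s_f <- rowsum(pre$n_j / d_j, pre$fam_of_ind)[, 1]
  c_f <- s2f / (1 + s2f * s_f)
  XtVX <- XtDX - crossprod(u_f * sqrt(c_f))
  XtVy <- XtDy - crossprod(u_f, v_f * c_f)
  ytVy <- ytDy - sum(c_f * v_f^2)
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(neg2ll = Inf))
  quad <- ytVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
  logdet <- (pre$N - length(pre$n_j)) * log(s2e) + sum(log(d_j)) +
    sum(log1p(s2f * s_f))
  list(neg2ll = logdet + quad + pre$N * log(2 * pi),
       beta = beta[, 1], XtVX = XtVX)
}

#' Fit the random-intercept linear mixed model of wellbeing means
#'
#' Maximum-likelihood (not REML) fit of
#' `Y = (b1 + u) + b2*wave + b3*sex + b4*age + b5*PEA + b6*rater + e`
#' with wave categorical (reference wave = baseline by default), female vs
#' male, parental educational attainment low/middle vs high, father vs
#' mother rater. The random structure is chosen by `nesting`: an individual
#' intercept nested within a family intercept (longitudinal twin cohorts), an
#' individual intercept only (cross-sectional cohorts), or none.
#'
#' Degrees of freedom for t statistics use a containment-style rule (terms
#' varying within individuals test against observation-level df, others
#' against group-level df) and are informative rather than exact.
#'
#' @param rows long observation table.
#' @param nesting random-intercept structure.
#' @param reference_wave wave acting as reference level (default: smallest
#'   observed wave).
#' @param covariates fixed-effect terms to include.
#' @return Object of class `lmm_fit` with a coefficient table (estimate, SE,
#'   t, approximate df, p), variance components, log-likelihood and the
#'   information needed for [estimated_marginal_means()].
#' @export
fit_random_intercept_lmm <- function(rows,
                                     nesting = c("individual-in-family",
                                                 "individual", "none"),
                                     reference_wave = NULL,
                                     covariates = c("wave", "sex", "age",
                                                    "pea", "rater")) {
  nesting <- match.arg(nesting)
  stopifnot(nrow(rows) > 0)
  if (is.null(reference_wave)) reference_wave <- min(rows$wave)
  y <- rows$wellbeing
  X <- lmm_design_matrix(rows, reference_wave, covariates)
  p <- ncol(X)
  N <- length(y)

  fam_ids <- if (nesting == "individual-in-family") rows$family_id else rows$individual_id
  ind <- factor(rows$individual_id)
  n_j <- as.integer(table(ind))
  ind_i <- as.integer(ind)
  # family index per individual (individuals are nested in families)
  fam_of_ind <- as.integer(factor(fam_ids))[match(levels(ind), rows$individual_id)]
  fam_of_ind <- as.integer(factor(fam_of_ind))

  near_unident <- nesting != "none" && all(n_j == 1L)
  if (near_unident) {
    warning("every individual has a single observation: the individual ",
            "random intercept is near-unidentified (only its sum with the ",
            "residual variance is determined)", call. = FALSE)
  }

  pre <- list(N = N, n_j = n_j, sum_y2 = sum(y^2), XtX = crossprod(X),
              Xty = crossprod(X, y), SyI = rowsum(y, ind_i)[, 1],
              SXI = rowsum(X, ind_i), fam_of_ind = fam_of_ind)

  use_fam <- nesting == "individual-in-family"
  use_ind <- nesting != "none"
  vy <- var(y)
  if (nesting == "none") {
    ev <- lmm_eval(pre, 0, 0, 1)
    # profile the single residual variance in closed form
    rss <- ev$neg2ll - N * log(2 * pi) # quad at s2e = 1
    s2e <- max(rss / N, 1e-10)         # guard the noise-free limit
    ev <- lmm_eval(pre, 0, 0, s2e)
    theta_hat <- log(s2e)
    opt_obj <- ev$neg2ll
    converged <- TRUE
    vars <- c(var_family = 0, var_individual = 0, var_residual = s2e)
  } else {
    k_active <- 1L + use_fam + use_ind
    obj <- function(theta) {
      i <- 1L
      s2f <- if (use_fam) exp(theta[i]) else 0
      if (use_fam) i <- i + 1L
      s2i <- if (use_ind) exp(theta[i]) else 0
      if (use_ind) i <- i + 1L
      s2e <- exp(theta[i])
      v <- lmm_eval(pre, s2f, s2i, s2e)$neg2ll
      if (!is.finite(v)) 1e10 else v
    }
    theta0 <- log(rep(max(vy, 1e-4) / k_active, k_active))
    o <- nlminb(theta0, obj,
                control = list(rel.tol = 1e-12, eval.max = 2000, iter.max = 1000))
    theta_hat <- o$par
    opt_obj <- o$objective
    converged <- o$convergence == 0
    i <- 1L
    s2f <- if (use_fam) exp(theta_hat[i]) else 0
    if (use_fam) i <- i + 1L
    s2i <- exp(theta_hat[i])
    s2e <- exp(theta_hat[i + 1L])
    ev <- lmm_eval(pre, s2f, s2i, s2e)
    vars <- c(var_family = s2f, var_individual = s2i, var_residual = s2e)
  }

  beta <- ev$beta
  vcov_beta <- solve(ev$XtVX)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  tval <- beta / se

  n_ind <- length(n_j)
  n_fam <- length(unique(fam_of_ind))
  within_ind <- vapply(seq_len(p), function(j) {
    m <- rowsum(X[, j], ind_i)[, 1] / n_j
    sum((X[, j] - m[ind_i])^2) > 1e-8
  }, logical(1))
  df <- ifelse(within_ind, max(N - n_ind, 1), max(n_ind - p, 1))
  pval <- 2 * stats::pt(-abs(tval), df)

  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      t = tval, df = df, p = pval, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, variances = vars,
                 minus2ll = opt_obj, loglik = -opt_obj / 2,
                 converged = converged, nesting = nesting,
                 near_unidentified_individual = near_unident,
                 n_obs = N, n_individuals = n_ind, n_families = n_fam,
                 reference_wave = reference_wave, covariates = covariates,
                 vcov_beta = vcov_beta,
                 wave_levels = sort(unique(rows$wave)),
                 frame = rows[, intersect(c("wave", "sex", "age", "pea", "rater"),
                                          names(rows)), drop = FALSE]),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Random-intercept LMM (ML), nesting: %s\n", x$nesting))
  cat(sprintf("n = %d observations, %d individuals, %d families; logLik = %.2f\n",
              x$n_obs, x$n_individuals, x$n_families, x$loglik))
  cat("Variance components:",
      paste(sprintf("%s = %.4f", names(x$variances), x$variances), collapse = ", "),
      "\n")
  if (x$near_unidentified_individual) {
    cat("NOTE: individual intercept near-unidentified (1 observation/individual)\n")
  }
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "t", "p")]),
                      digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Coefficient lookup helper for `lmm_fit`
#' @param object an `lmm_fit`.
#' @param ... unused.
#' @export
coef.lmm_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Estimated marginal means of wellbeing per survey wave
#'
#' Model-predicted mean per wave with all other covariates averaged over
#' their observed sample distribution (sex, PEA and rater at observed
#' proportions, age at its observed values), i.e. the average prediction over
#' the sample with the wave forced to each level in turn. Invariant to
#' reference-level recoding of the categorical covariates.
#'
#' @param fit an `lmm_fit`.
#' @param waves waves to evaluate (default: all waves observed in the data).
#' @return Data frame with columns `wave` and `emm`.
#' @export
estimated_marginal_means <- function(fit, waves = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  observed <- sort(unique(fit$frame$wave))
  if (is.null(waves)) waves <- observed
  missing_w <- setdiff(waves, observed)
  if (length(missing_w)) {
    stop("wave(s) absent from the fitted data: ", paste(missing_w, collapse = ", "))
  }
  beta <- coef(fit)
  out <- vapply(waves, function(w) {
    fr <- fit$frame
    fr$wave <- w
    Xw <- lmm_design_matrix(fr, fit$reference_wave, fit$covariates,
                            wave_levels = fit$wave_levels, check = FALSE)
    # terms dropped during fitting (constant columns) contribute nothing
    common <- intersect(colnames(Xw), names(beta))
    mean(Xw[, common, drop = FALSE] %*% beta[common])
  }, numeric(1))
  data.frame(wave = waves, emm = out)
}

#' Select each individual's baseline (latest pre-pandemic) record
#'
#' For individuals with several pre-pandemic measurements (wave 0 rows), the
#' most recent one is kept to minimize the time gap to the pandemic
#' measurements; an optional `year` column orders them. Individuals without
#' any pre-pandemic record contribute no baseline row. Ties on the date
#' resolve deterministically to the first record in table order and are
#' flagged in the `ties` attribute.
#'
#' @param rows long observation table (one or several individuals).
#' @return The selected baseline rows (one per individual present), with
#'   attribute `ties` listing individuals whose selection was tie-broken.
#' @export
select_baseline <- function(rows) {
  pre <- rows[rows$wave == 0, , drop = FALSE]
  if (!nrow(pre)) {
    attr(pre, "ties") <- character(0)
    return(pre)
  }
  key <- if ("year" %in% names(pre)) pre$year else rep(0, nrow(pre))
  ord <- order(pre$individual_id, -key) # stable: ties keep record order
  pre <- pre[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(pre$individual_id)
  max_count <- tapply(key, pre$individual_id, function(k) sum(k == max(k)))
  tied_ids <- names(max_count)[max_count > 1]
  out <- pre[first, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ties") <- tied_ids
  out
}
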