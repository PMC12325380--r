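# Univariate twin-model machinery: expected covariances, twin correlations,
# the ACE/ADE model-family rule, and raw-data ML fitting of univariate models.

#' Expected twin-pair covariance of a univariate ACE/ADE model
#'
#' MZ twins share essentially all segregating genes and DZ twins half on
#' average, so the cross-twin covariance is `k_A*a2 + c2 + k_D*d2` with
#' `k_A = 1` (MZ) or `0.5` (DZ) and `k_D = 1` (MZ) or `0.25` (DZ); the
#' diagonal is the total phenotypic variance.
#'
#' @param params an [ace_params()] object. C and D may not both be nonzero
#'   (ACE and ADE are alternative model families).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 2 x 2 covariance matrix.
#' @export
#' @examples
#' expected_cov_univariate(ace_params(0.38, 0.52, 0.17), "MZ")
expected_cov_univariate <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "ace_params"))
  zygosity <- match.arg(zygosity)
  if (params$c2 > 0 && params$d2 > 0) {
    stop("c2 and d2 may not both be nonzero: ACE and ADE are alternative families")
  }
  k_a <- if (zygosity == "MZ") 1 else 0.5
  k_d <- if (zygosity == "MZ") 1 else 0.25
  v <- total_variance(params)
  cv <- k_a * params$a2 + params$c2 + k_d * params$d2
  matrix(c(v, cv, cv, v), 2, 2)
}

#' Choose between the ACE and ADE model families from twin correlations
#'
#' An ACE model is indicated when the MZ correlation is lower than twice the
#' DZ correlation (shared-environment effects); an ADE model when it is
#' higher (non-additive genetic effects). Ties resolve to ACE, since C and D
#' are not jointly identifiable in the classical design.
#'
#' @param tc a [twin_correlations()] result (or any list with `r_mz`, `r_dz`).
#' @return `"ACE"` or `"ADE"`.
#' @export
#' @examples
#' choose_ace_or_ade(list(r_mz = 0.83, r_dz = 0.67)) # "ACE"
choose_ace_or_ade <- function(tc) {
  r_mz <- tc$r_mz
  r_dz <- tc$r_dz
  if (is.null(r_mz) || is.null(r_dz) || is.na(r_mz) || is.na(r_dz)) {
    stop("twin correlations are undefined; cannot choose a model family")
  }
  if (r_mz > 2 * r_dz) "ADE" else "ACE"
}

#' Reshape long observation rows into one row per twin pair
#'
#' Selects one rating per child (mother preferred over father when both are
#' present, `other` raters excluded; or a single requested rater) in one
#' period and pairs twins within family. Twin order follows individual id,
#' which is arbitrary by design.
#'
#' @param data long observation table.
#' @param period period label to extract.
#' @param rater `"preferred"` (mother if present, else father) or a specific
#'   rater.
#' @return Data frame with columns `family_id`, `zygosity`, `y1`, `y2` (`NA`
#'   for an unobserved twin).
#' @export
twin_pairs <- function(data, period, rater = "preferred") {
  d <- data[data$period == period & data$zygosity %in% c("MZ", "DZ"), , drop = FALSE]
  d <- if (identical(rater, "preferred")) {
    d <- d[d$rater %in% c("mother", "father"), , drop = FALSE]
    d <- d[order(d$individual_id, match(d$rater, c("mother", "father")), d$wave), ]
    d[!duplicated(d$individual_id), , drop = FALSE]
  } else {
    d <- d[d$rater == rater, , drop = FALSE]
    d <- d[order(d$individual_id, d$wave), ]
    d[!duplicated(d$individual_id), , drop = FALSE]
  }
  fams <- unique(d[, c("family_id", "zygosity")])
  ord <- stats::ave(seq_len(nrow(d)), d$family_id,
                    FUN = function(ix) rank(d$individual_id[ix], ties.method = "first"))
  d <- d[ord <= 2, , drop = FALSE]
  ord <- ord[ord <= 2]
  wide <- data.frame(family_id = fams$family_id, zygosity = fams$zygosity,
                     y1 = NA_real_, y2 = NA_real_)
  m <- match(d$family_id, wide$family_id)
  wide$y1[m[ord == 1]] <- d$wellbeing[ord == 1]
  wide$y2[m[ord == 2]] <- d$wellbeing[ord == 2]
  wide[!(is.na(wide$y1) & is.na(wide$y2)), , drop = FALSE]
}

#' Twin correlations by zygosity
#'
#' Pearson correlation of twin-1 vs twin-2 scores per zygosity group with
#' pairs double-entered symmetrically (each complete pair contributes in both
#' orders), since twin order is arbitrary.
#'
#' @param data long observation table, or a wide pair table from
#'   [twin_pairs()].
#' @param rater,period forwarded to [twin_pairs()] when `data` is long.
#' @return Object of class `twin_correlations`: `r_mz`, `r_dz`, pair counts,
#'   and an `estimable` flag per zygosity (at least 2 complete pairs).
#' @export
twin_correlations <- function(data, rater = "preferred", period = NULL) {
  wide <- if (all(c("y1", "y2") %in% names(data))) {
    data
  } else {
    twin_pairs(data, period = period, rater = rater)
  }
  one <- function(z) {
    w <- wide[wide$zygosity == z & complete.cases(wide[, c("y1", "y2")]), ]
    n <- nrow(w)
    if (n < 2 || sd(c(w$y1, w$y2)) == 0) {
      return(list(r = NA_real_, n = n, estimable = FALSE))
    }
    list(r = cor(c(w$y1, w$y2), c(w$y2, w$y1)), n = n, estimable = TRUE)
  }
  mz <- one("MZ")
  dz <- one("DZ")
  structure(list(r_mz = mz$r, r_dz = dz$r, n_mz = mz$n, n_dz = dz$n,
                 estimable = c(MZ = mz$estimable, DZ = dz$estimable)),
            class = "twin_correlations")
}

#' @export
print.twin_correlations <- function(x, ...) {
  cat(sprintf("Twin correlations (double-entered): r_MZ = %.3f (n = %d), r_DZ = %.3f (n = %d)\n",
              x$r_mz, x$n_mz, x$r_dz, x$n_dz))
  invisible(x)
}

#' Fit a univariate twin model by raw-data maximum likelihood
#'
#' Fits ACE, ADE or reduced (AE/CE/E) univariate models to twin-pair data by
#' full-information maximum likelihood: pairs with one missing co-twin
#' contribute their observed margin. Variance components are parameterized on
#' the standard-deviation scale internally (so reported variances are bounded
#' at zero) and the mean is a single free intercept. Optimization uses
#' quasi-Newton search with jittered restarts.
#'
#' @param model `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param data wide pair table (`y1`, `y2`, `zygosity`) from [twin_pairs()],
#'   or a long observation table (then `period`/`rater` select the slice).
#' @param period,rater forwarded to [twin_pairs()] for long input.
#' @param start optional named start values on the variance scale.
#' @param n_restarts jittered optimizer restarts (first start unjittered).
#' @param se compute observed-information standard errors.
#' @param ... unused.
#' @return A `twin_fit` with estimates `mu` and the model's variance
#'   components (`a2`, `c2` or `d2`, `e2`).
#' @export
fit_model <- function(model, data, ...) UseMethod("fit_model")

#' @rdname fit_model
#' @export
fit_model.character <- function(model, data, period = NULL, rater = "preferred",
                                start = NULL, n_restarts = 5, se = TRUE, ...) {
  model <- match.arg(model, c("ACE", "ADE", "AE", "CE", "E"))
  wide <- if (all(c("y1", "y2") %in% names(data))) data
          else twin_pairs(data, period = period, rater = rater)
  y <- as.matrix(wide[, c("y1", "y2")])
  if (nrow(y) == 0) stop("no twin pairs in data")
  yv <- var(c(y), na.rm = TRUE)
  if (!is.finite(yv) || yv <= 0) stop("zero-variance data: model is degenerate")
  comp <- switch(model, ACE = c("a2", "c2", "e2"), ADE = c("a2", "d2", "e2"),
                 AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  zyg <- factor(wide$zygosity, levels = c("MZ", "DZ"))
  pat <- fiml_patterns(y, as.integer(zyg))
  k_a <- c(1, 0.5)
  k_d <- c(1, 0.25)

  build_sigma <- function(v) { # v: named variances
    a2 <- v["a2"] %||% 0
    c2 <- v["c2"] %||% 0
    d2 <- v["d2"] %||% 0
    e2 <- v["e2"]
    a2 <- ifelse(is.na(a2), 0, a2); c2 <- ifelse(is.na(c2), 0, c2)
    d2 <- ifelse(is.na(d2), 0, d2)
    lapply(1:2, function(g) {
      tot <- a2 + c2 + d2 + e2
      cv <- k_a[g] * a2 + c2 + k_d[g] * d2
      matrix(c(tot, cv, cv, tot), 2, 2)
    })
  }
  neg2ll <- function(par) {
    mu <- par[1]
    v <- setNames(par[-1]^2, comp)
    sig <- build_sigma(v)
    -2 * fiml_loglik_resid(y - mu, sig, pat)
  }

  if (is.null(start)) {
    mu0 <- mean(y, na.rm = TRUE)
    s0 <- setNames(rep(yv / length(comp), length(comp)), comp)
  } else {
    mu0 <- start["mu"] %||% mean(y, na.rm = TRUE)
    s0 <- start[comp]
  }
  par0 <- c(mu0, sqrt(pmax(unname(s0), 1e-4)))
  opt <- ml_fit(neg2ll, par0, n_restarts = n_restarts,
                restart_seed = substream_seed(7L, model))
  est <- c(mu = opt$par[1], setNames(opt$par[-1]^2, comp))
  pm <- c(list(mu = list(index = 1L, trans = "id")),
          setNames(lapply(seq_along(comp),
                          function(i) list(index = i + 1L, trans = "sq")), comp))
  se_v <- NULL
  if (se) {
    H <- num_hessian(neg2ll, opt$par)
    cv <- tryCatch(2 * solve(H), error = function(e) NULL) # -2lnL Hessian = 2 * information
    if (!is.null(cv)) {
      sd_int <- sqrt(pmax(diag(cv), 0))
      # delta method: var components are u^2, d(u^2)/du = 2u
      se_v <- c(sd_int[1], abs(2 * opt$par[-1]) * sd_int[-1])
      names(se_v) <- names(est)
    }
  }
  boot_fn <- function(n_boot, seed) {
    with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        ix <- unlist(lapply(split(seq_len(nrow(wide)), wide$zygosity),
                            function(g) sample(g, length(g), replace = TRUE)))
        f <- fit_model(model, wide[ix, , drop = FALSE],
                       n_restarts = 1, se = FALSE)
        f$estimates[names(est)]
      }, numeric(length(est))))
    })
  }
  new_twin_fit(model = paste0("univariate ", model),
               estimates = est, minus2ll = opt$objective,
               converged = opt$converged,
               n_obs = nrow(y), n_par = length(par0), se = se_v,
               par = opt$par, neg2ll = neg2ll, profile_map = pm,
               boot_fn = boot_fn,
               extra = list(n_mz = sum(zyg == "MZ"), n_dz = sum(zyg == "DZ")))
}
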