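# Fit-result container shared by all maximum-likelihood model fits, plus
# likelihood-based confidence intervals and likelihood-ratio tests.

new_twin_fit <- function(model, estimates, minus2ll, converged, n_obs, n_par,
                         se = NULL, par = NULL, neg2ll = NULL,
                         profile_map = NULL, lower = NULL, upper = NULL,
                         boot_fn = NULL, extra = list()) {
  structure(list(model = model, estimates = estimates, se = se,
                 minus2ll = minus2ll, loglik = -minus2ll / 2,
                 converged = converged, n_obs = n_obs, n_par = n_par,
                 par = par, neg2ll = neg2ll, profile_map = profile_map,
                 lower = lower, upper = upper, boot_fn = boot_fn,
                 extra = extra),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat("Maximum-likelihood fit:", x$model, "\n")
  cat(sprintf("-2 log-likelihood: %.4f  (n = %d units, %d free parameters)\n",
              x$minus2ll, x$n_obs, x$n_par))
  if (!x$converged) cat("WARNING: optimizer did not report clean convergence\n")
  est <- data.frame(estimate = round(x$estimates, digits))
  if (!is.null(x$se)) est$se <- round(x$se[names(x$estimates)], digits)
  print(est)
  invisible(x)
}

refit_with_fixed <- function(fit, index, value) {
  p0 <- fit$par
  lo <- fit$lower %||% rep(-Inf, length(p0))
  up <- fit$upper %||% rep(Inf, length(p0))
  obj <- function(po) {
    p <- p0
    p[-index] <- po
    p[index] <- value
    v <- tryCatch(fit$neg2ll(p), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  if (length(p0) == 1L) return(obj(numeric(0)))
  o <- tryCatch(nlminb(p0[-index], obj, lower = lo[-index], upper = up[-index],
                       control = list(rel.tol = 1e-12, eval.max = 5000, iter.max = 2000)),
                error = function(e) NULL)
  if (is.null(o)) Inf else o$objective
}

#' Likelihood-based confidence interval for one reported parameter
#'
#' Profiles the -2 log-likelihood over a single reported parameter: the
#' interval is the set of values at which the profiled -2 log-likelihood rises
#' no more than `qchisq(level, 1)` (3.841 for 95%) above its minimum. Variance
#' components are bounded below at zero, so the lower limit may be exactly 0.
#' If profiling cannot bracket a limit (e.g. a flat likelihood), a seeded
#' nonparametric bootstrap is used instead, with a warning, provided the fit
#' carries a resampling routine.
#'
#' @param fit a `twin_fit` object from [fit_model()] or [fit_psychometric()].
#' @param parameter name of a reported parameter (see `fit$estimates`).
#' @param level confidence level, default 0.95.
#' @param n_boot bootstrap resamples for the fallback route.
#' @param boot_seed seed for the bootstrap fallback.
#' @return Named numeric `c(lower, upper)`, with attribute `method` equal to
#'   `"profile"` or `"bootstrap"`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95, n_boot = 200, boot_seed = 1) {
  stopifnot(inherits(fit, "twin_fit"))
  if (!fit$converged) warning("profiling a fit without clean convergence")
  est <- unname(fit$estimates[parameter])
  if (is.na(est)) stop("unknown parameter: ", parameter)
  info <- fit$profile_map[[parameter]]
  if (is.null(info) || is.null(fit$neg2ll)) {
    return(boot_ci(fit, parameter, level, n_boot, boot_seed,
                   reason = "parameter is not profileable in this fit"))
  }
  crit <- qchisq(level, 1)
  to_internal <- switch(info$trans, sq = function(v) sqrt(pmax(v, 0)), identity)
  dev <- function(v) refit_with_fixed(fit, info$index, to_internal(v)) - fit$minus2ll
  se_guess <- if (!is.null(fit$se) && is.finite(fit$se[parameter]) && fit$se[parameter] > 0) {
    unname(fit$se[parameter])
  } else {
    0.25 * max(abs(est), 0.1)
  }
  bounded_below <- identical(info$trans, "sq")

  find_limit <- function(direction) {
    step <- se_guess
    v_in <- est
    for (j in 1:30) {
      v_out <- est + direction * step
      if (bounded_below && v_out <= 0) v_out <- 0
      d <- dev(v_out)
      if (is.finite(d) && d >= crit) {
        r <- uniroot(function(v) dev(v) - crit, lower = min(v_in, v_out),
                     upper = max(v_in, v_out), tol = 1e-6)
        return(r$root)
      }
      if (bounded_below && v_out == 0) return(0)
      v_in <- v_out
      step <- step * 2
    }
    NA_real_
  }

  lo <- find_limit(-1)
  hi <- find_limit(+1)
  if (is.na(lo) || is.na(hi)) {
    return(boot_ci(fit, parameter, level, n_boot, boot_seed,
                   reason = "profile failed to bracket a limit"))
  }
  structure(setNames(c(lo, hi), c("lower", "upper")), method = "profile")
}

boot_ci <- function(fit, parameter, level, n_boot, boot_seed, reason) {
  if (is.null(fit$boot_fn)) {
    stop("cannot form an interval: ", reason,
         " and the fit has no bootstrap routine", call. = FALSE)
  }
  warning(reason, "; falling back to a seeded nonparametric bootstrap (",
          n_boot, " resamples)", call. = FALSE)
  est <- fit$boot_fn(n_boot, boot_seed)
  qs <- stats::quantile(est[, parameter], c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(setNames(qs, c("lower", "upper")), method = "bootstrap")
}

#' Likelihood-ratio test of nested maximum-likelihood fits
#'
#' @param full fit of the less constrained model.
#' @param nested fit of the constrained (nested) model.
#' @return List with `statistic` (difference in -2 log-likelihood), `df`
#'   (difference in free parameters) and `p` (upper chi-square tail).
#' @export
lrt <- function(full, nested) {
  stopifnot(inherits(full, "twin_fit"), inherits(nested, "twin_fit"))
  if (nested$n_par >= full$n_par) {
    stop("'nested' must have fewer free parameters than 'full'")
  }
  stat <- nested$minus2ll - full$minus2ll
  tol <- 1e-4 * max(1, abs(full$minus2ll))
  if (stat < -tol) {
    stop(sprintf(paste0("nested model fits better than the full model ",
                        "(delta -2lnL = %.6f): optimizer failure"), stat))
  }
  stat <- max(stat, 0)
  df <- full$n_par - nested$n_par
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
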