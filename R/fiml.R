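# Raw-data (full-information) multivariate-normal likelihood machinery.
#
# Units (twin families) are grouped by missing-data pattern and covariance
# group (zygosity); within a pattern the covariance submatrix is factored once
# and the quadratic forms are evaluated for all units in one matrix product.

# Precompute the pattern grouping for a data matrix. `group` indexes which
# covariance matrix applies to each row (e.g. zygosity).
fiml_patterns <- function(y, group = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  k <- ncol(y)
  if (is.null(group)) group <- rep(1L, n)
  gf <- factor(group)
  g <- as.integer(gf)
  obs <- !is.na(y)
  if (any(rowSums(obs) == 0L)) {
    stop("every unit must have at least one observed variable", call. = FALSE)
  }
  code <- as.vector(obs %*% 2^(seq_len(k) - 1))
  key <- paste0(g, "|", code)
  idx <- split(seq_len(n), key)
  pats <- lapply(idx, function(rows) {
    list(rows = rows, cols = which(obs[rows[1L], ]), group = g[rows[1L]])
  })
  structure(list(patterns = unname(pats), n = n, k = k,
                 n_groups = nlevels(gf), group_levels = levels(gf),
                 n_observed = sum(obs)),
            class = "fiml_patterns")
}

# Log-likelihood of residuals (y - mu, NA where missing) under per-group
# covariance matrices, summed over all units. Returns -Inf if any observed
# submatrix is not positive definite (the optimizer treats this as a barrier).
fiml_loglik_resid <- function(resid, sigma_list, pat) {
  ll <- 0
  for (p in pat$patterns) {
    S <- sigma_list[[p$group]][p$cols, p$cols, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || any(diag(ch) < 1e-10)) return(-Inf)
    m <- length(p$cols)
    R <- resid[p$rows, p$cols, drop = FALSE]
    quad <- rowSums((R %*% chol2inv(ch)) * R)
    ll <- ll - 0.5 * (length(p$rows) * (m * log(2 * pi) + 2 * sum(log(diag(ch)))) +
                        sum(quad))
  }
  ll
}

#' Raw-data multivariate-normal log-likelihood with missing data
#'
#' Sums, over independent units (rows), the log-density of each unit's
#' observed subvector under a multivariate-normal model. This is the raw-data
#' ("full information") maximum-likelihood objective used by all twin-model
#' fits: missing entries are marginalized exactly by dropping the
#' corresponding rows/columns of the mean and covariance, so no unit is
#' listwise-deleted. With complete data it equals the dense
#' multivariate-normal log-likelihood.
#'
#' @param y numeric matrix (units x variables), `NA` where unobserved; a
#'   vector is treated as a one-column matrix.
#' @param mu numeric matrix of the same shape (or a length-k vector recycled
#'   across units) of model-implied means.
#' @param sigma a k x k covariance matrix, or a list of such matrices when
#'   `group` is supplied.
#' @param group optional vector (length `nrow(y)`) selecting which covariance
#'   matrix applies to each unit, e.g. zygosity.
#' @return The scalar log-likelihood; `-Inf` if an observed submatrix is not
#'   positive definite.
#' @export
#' @examples
#' fiml_loglik(0, 0, matrix(1)) # standard normal at its mode: -0.5*log(2*pi)
fiml_loglik <- function(y, mu, sigma, group = NULL) {
  y <- as.matrix(y)
  if (is.matrix(sigma)) sigma <- list(sigma)
  if (is.null(group)) group <- rep(1L, nrow(y))
  if (!is.matrix(mu)) {
    mu <- matrix(mu, nrow(y), ncol(y), byrow = length(mu) == ncol(y) && ncol(y) > 1)
  }
  stopifnot(identical(dim(mu), dim(y)))
  gi <- as.integer(factor(group))
  if (max(gi) > length(sigma)) stop("more groups than covariance matrices")
  pat <- fiml_patterns(y, gi)
  fiml_loglik_resid(y - mu, sigma, pat)
}

# Quasi-Newton minimization of a -2*log-likelihood objective with multiple
# jittered restarts. Non-finite objective values are mapped to a large barrier.
ml_fit <- function(neg2ll, start, n_restarts = 5, jitter = 0.25,
                   lower = -Inf, upper = Inf, restart_seed = 101, control = list()) {
  safe <- function(p) {
    v <- tryCatch(neg2ll(p), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- modifyList(list(eval.max = 10000, iter.max = 5000,
                          rel.tol = 1e-12, x.tol = 1.5e-10), control)
  best <- NULL
  n_ok <- 0L
  starts <- with_seed(restart_seed, {
    lapply(seq_len(n_restarts), function(r) {
      if (r == 1) start
      else start * (1 + jitter * rnorm(length(start))) + 0.1 * jitter * rnorm(length(start))
    })
  })
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    f <- tryCatch(nlminb(s, safe, lower = lower, upper = upper, control = ctrl),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$objective)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || f$objective < best$objective - 1e-9) best <- f
  }
  if (is.null(best)) stop("optimization failed in all restarts", call. = FALSE)
  list(par = best$par, objective = best$objective,
       converged = best$convergence == 0 || n_ok > 1L,
       nlminb_convergence = best$convergence,
       message = best$message, n_restarts_used = n_ok)
}

# Central-difference Hessian of f at x (used for observed-information SEs).
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- h[i]
      ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}
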