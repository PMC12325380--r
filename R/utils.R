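#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a pipeline run flows from one root seed; each stage draws
#' from its own substream so partial reruns of a stage reproduce exactly.
#' The sub-seed is a deterministic 31-bit hash of the root seed and the stage
#' name.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "simulate")
substream_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(root_seed) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 69069 + ch) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Symmetry + positive semi-definiteness check with a small tolerance.
is_psd <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < 1e-8 &&
    min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values) >
      -tol * max(1, max(abs(m)))
}

check_psd <- function(m, name) {
  if (!is_psd(m)) {
    stop(sprintf("component matrix '%s' is not symmetric positive semi-definite", name),
         call. = FALSE)
  }
  invisible(m)
}

# Lower-triangular (incl. diagonal) vector <-> matrix helpers used by the
# matrix-square-root parameterization Sigma = L L'.
ltri_to_mat <- function(v, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

mat_to_ltri <- function(L) L[lower.tri(L, diag = TRUE)]

# Nearest-PD projection (eigenvalue floor) then lower Cholesky factor; used to
# turn moment-based starting matrices into unconstrained parameters.
psd_chol_start <- function(S, floor = 1e-3) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  Sp <- e$vectors %*% (vals * t(e$vectors))
  t(chol((Sp + t(Sp)) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical column set of the long observation table.
observation_columns <- function() {
  c("family_id", "individual_id", "zygosity", "wave", "period", "rater",
    "sex", "age", "pea", "wellbeing")
}

default_periods <- function() c("pre", "early", "late", "post")

#' Map survey waves to pandemic periods
#'
#' Default collapsing: wave 0 (pre-pandemic baseline) -> `pre`, waves 1-2 ->
#' `early`, waves 3-4 -> `late`, waves 5-6 (and later) -> `post`.
#'
#' @param wave integer vector of wave numbers (0 = pre-pandemic baseline).
#' @param map named list giving the wave numbers belonging to each period.
#' @return Character vector of period labels.
#' @export
wave_to_period <- function(wave,
                           map = list(pre = 0L, early = 1:2, late = 3:4, post = 5:7)) {
  out <- rep(NA_character_, length(wave))
  for (p in names(map)) out[wave %in% map[[p]]] <- p
  if (anyNA(out)) stop("wave(s) not covered by the period map: ",
                       paste(unique(wave[is.na(out)]), collapse = ", "))
  out
}
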