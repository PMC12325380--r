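# Pipeline driver: simulate -> twin correlations -> correlated factors ->
# multi-rater -> mixed model, from one seeded configuration, writing
# fixed-format CSV tables plus a run log so reruns are byte-identical.

#' Read the canonical long-format observation CSV
#'
#' Validates the header against the canonical schema (unknown extra columns
#' are preserved but ignored by the fitters) and excludes rows whose
#' wellbeing score lies outside the 0-10 ladder, with a warning and an
#' `excluded` attribute carrying the count.
#'
#' @param path CSV file path.
#' @return Observation data frame with attribute `excluded`.
#' @export
read_long_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- observation_columns()
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !is.na(d$wellbeing) & (d$wellbeing < 0 | d$wellbeing > 10)
  if (any(bad)) {
    warning(sum(bad), " row(s) with wellbeing outside [0, 10] excluded")
    d <- d[!bad, , drop = FALSE]
    rownames(d) <- NULL
  }
  attr(d, "excluded") <- sum(bad)
  d
}

#' Write the canonical long-format observation CSV
#'
#' Writes the canonical columns (plus any extras) with a fixed numeric
#' format so `read_long_csv(write_long_csv(x))` round-trips the canonical
#' columns and identical inputs yield byte-identical files.
#'
#' @param rows observation data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_long_csv <- function(rows, path) {
  out <- rows
  for (cl in c("age", "wellbeing")) {
    if (is.numeric(out[[cl]])) out[[cl]] <- sprintf("%.6g", out[[cl]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input `"simulate"` or a path to a long-format CSV.
#' @param stages which analysis stages to run (`simulate` is implied by
#'   `input = "simulate"`).
#' @param seed root seed; every stage derives its own substream from it.
#' @param sim_config a [simulation_config()] for the simulate stage
#'   (its seed is replaced by the `simulate` substream of `seed`).
#' @param lmm_spec,lmm_design generating model and design for the mixed-model
#'   stage when input is simulated; with CSV input the mixed model is fitted
#'   to the rows as given.
#' @param periods period labels in order.
#' @param digits rounding applied to emitted tables (output only).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "simulate",
                            stages = c("twin_correlations", "correlated_factors",
                                       "multirater", "lmm"),
                            seed = 1L,
                            sim_config = NULL,
                            lmm_spec = lmm_spec_ntr(),
                            lmm_design = lmm_design_ntr(500),
                            periods = default_periods(),
                            digits = 2) {
  known <- c("twin_correlations", "correlated_factors", "multirater", "lmm")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!identical(input, "simulate") && !file.exists(input)) {
    stop("input must be \"simulate\" or an existing CSV path")
  }
  if (is.null(sim_config)) {
    sim_config <- simulation_config(
      n_mz_pairs = 400, n_dz_pairs = 400,
      multirater = setNames(lapply(periods, multirater_params_wellbeing), periods),
      seed = 1L)
  }
  structure(list(input = input, stages = stages, seed = as.integer(seed),
                 sim_config = sim_config, lmm_spec = lmm_spec,
                 lmm_design = lmm_design, periods = periods, digits = digits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Recognized keys: `input`, `stages`, `seed`, `n_mz_pairs`, `n_dz_pairs`,
#' `multirater` (logical: attach the default per-period rater-specific
#' components), `lmm_cohort` (`ntr`, `klik` or `dreams`), `lmm_n`, `digits`.
#' Unknown keys are an error (fail before any computation).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("input", "stages", "seed", "n_mz_pairs", "n_dz_pairs",
             "multirater", "lmm_cohort", "lmm_n", "digits")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  periods <- default_periods()
  mr <- if (isTRUE(cfg$multirater %||% TRUE)) {
    setNames(lapply(periods, multirater_params_wellbeing), periods)
  } else {
    NULL
  }
  sim <- simulation_config(n_mz_pairs = cfg$n_mz_pairs %||% 400,
                           n_dz_pairs = cfg$n_dz_pairs %||% 400,
                           multirater = mr, seed = 1L)
  cohort <- cfg$lmm_cohort %||% "ntr"
  spec <- switch(cohort, ntr = lmm_spec_ntr(), klik = lmm_spec_klik(),
                 dreams = lmm_spec_dreams(),
                 stop("unknown lmm_cohort: ", cohort))
  design <- switch(cohort,
                   ntr = lmm_design_ntr(cfg$lmm_n %||% 500),
                   klik = lmm_design_klik(cfg$lmm_n %||% 1000),
                   dreams = lmm_design_dreams(cfg$lmm_n %||% 1000))
  pipeline_config(input = cfg$input %||% "simulate",
                  stages = cfg$stages %||% c("twin_correlations",
                                             "correlated_factors",
                                             "multirater", "lmm"),
                  seed = cfg$seed %||% 1L, sim_config = sim,
                  lmm_spec = spec, lmm_design = design,
                  digits = cfg$digits %||% 2)
}

fmt_table <- function(df, digits) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- sprintf(paste0("%.", digits, "f"), df[[cl]])
  }
  df
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order on simulated or CSV
#' input and collects their tables: per-period twin and cross-rater
#' correlations, unstandardized and standardized correlated-factors tables,
#' multi-rater view shares, mixed-model coefficients and estimated marginal
#' means, plus a run log carrying the seed, likelihoods and convergence
#' flags. A stage that errors marks the bundle and dependent outputs are
#' skipped. Reruns with the same configuration and seed are byte-identical
#' once written by [write_tables()].
#'
#' @param config a [pipeline_config()].
#' @return Object of class `pipeline_bundle`: named tables, `log` (character
#'   lines), and `failed` (named stage errors, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("root_seed: %d", config$seed),
           sprintf("input: %s", config$input))
  tables <- list()
  failed <- list()

  rows <- tryCatch({
    if (identical(config$input, "simulate")) {
      sc <- config$sim_config
      sc$seed <- substream_seed(config$seed, "simulate")
      r <- simulate_twin_cohort(sc)
      log <- c(log, sprintf("simulate: %d rows, seed %d", nrow(r), sc$seed))
      r
    } else {
      r <- read_long_csv(config$input)
      log <- c(log, sprintf("read: %d rows (%d excluded)", nrow(r),
                            attr(r, "excluded")))
      r
    }
  }, error = function(e) {
    failed$input <<- conditionMessage(e)
    NULL
  })
  tables$cohort <- rows

  if (!is.null(rows) && "twin_correlations" %in% config$stages) {
    tables$table5 <- tryCatch({
      tc <- do.call(rbind, lapply(config$periods, function(p) {
        x <- twin_correlations(rows, period = p)
        data.frame(period = p, r_mz = x$r_mz, r_dz = x$r_dz,
                   n_mz = x$n_mz, n_dz = x$n_dz,
                   family = choose_ace_or_ade(x), stringsAsFactors = FALSE)
      }))
      log <- c(log, "twin_correlations: ok")
      tc
    }, error = function(e) {
      failed$twin_correlations <<- conditionMessage(e)
      NULL
    })
  }

  if (!is.null(rows) && "correlated_factors" %in% config$stages) {
    res <- tryCatch({
      cf <- fit_correlated_factors(rows, periods = config$periods)
      tabs <- reproduce_tables(cf, digits = config$digits)
      log <- c(log, sprintf("correlated_factors: -2lnL %.4f converged %s",
                            cf$fit$minus2ll, cf$fit$converged))
      tabs
    }, error = function(e) {
      failed$correlated_factors <<- conditionMessage(e)
      NULL
    })
    tables$table3 <- res$unstandardized
    tables$table4 <- res$standardized
  }

  if (!is.null(rows) && "multirater" %in% config$stages) {
    tables$views <- tryCatch({
      vw <- do.call(rbind, lapply(config$periods, function(p) {
        ps <- fit_psychometric(rows, p, n_restarts = 2)
        sat <- fit_constrained_saturated(rows, p, n_restarts = 1)
        log <<- c(log, sprintf(
          "multirater[%s]: -2lnL %.4f constraint p %.4f", p,
          ps$fit$minus2ll, sat$lrt$p))
        data.frame(period = p,
                   cross_rater_correlation = sat$cross_rater_correlation,
                   constraint_p = sat$lrt$p,
                   common_share_mother = ps$views$mother$common_share,
                   common_share_father = ps$views$father$common_share,
                   combined_common_share = ps$views$combined_common_share,
                   bias_share_mother = ps$views$mother$bias_share,
                   bias_share_father = ps$views$father$bias_share,
                   stringsAsFactors = FALSE)
      }))
      vw
    }, error = function(e) {
      failed$multirater <<- conditionMessage(e)
      NULL
    })
  }

  if ("lmm" %in% config$stages) {
    res <- tryCatch({
      lrows <- if (identical(config$input, "simulate")) {
        simulate_lmm_cohort(config$lmm_spec, config$lmm_design,
                            seed = substream_seed(config$seed, "lmm"))
      } else {
        rows
      }
      nest <- if (config$lmm_design$type == "twin") "individual-in-family" else "individual"
      fit <- suppressWarnings(fit_random_intercept_lmm(lrows, nesting = nest))
      log <- c(log, sprintf("lmm: logLik %.4f converged %s",
                            fit$loglik, fit$converged))
      list(coefs = fit$coefficients,
           emm = estimated_marginal_means(fit))
    }, error = function(e) {
      failed$lmm <<- conditionMessage(e)
      NULL
    })
    tables$table2 <- res$coefs
    tables$emm <- res$emm
  }

  structure(list(tables = tables, log = log, failed = failed,
                 seed = config$seed, digits = config$digits),
            class = "pipeline_bundle")
}

#' Write a pipeline bundle to an output directory
#'
#' Emits one CSV per produced table (`cohort.csv`, `table2.csv` ...
#' `table5.csv`, `table3_std.csv` as `table4.csv`, `views.csv`, `emm.csv`)
#' with numbers rounded to the configured digits (internal precision is
#' never rounded), plus `run_log.txt` including the seed.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(bundle$tables$cohort)) {
    p <- file.path(dir, "cohort.csv")
    write_long_csv(bundle$tables$cohort, p)
    written <- c(written, p)
  }
  for (nm in c("table2", "table3", "table4", "table5", "views", "emm")) {
    tb <- bundle$tables[[nm]]
    if (is.null(tb)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(fmt_table(tb, bundle$digits), p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  log <- c(bundle$log,
           if (length(bundle$failed)) {
             paste0("FAILED ", names(bundle$failed), ": ",
                    unlist(bundle$failed))
           })
  writeLines(log, file.path(dir, "run_log.txt"))
  written <- c(written, file.path(dir, "run_log.txt"))
  invisible(written)
}
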