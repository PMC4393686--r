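## Orchestration of the full study analysis on a cohort table:
## preprocessing -> descriptives -> phenotypic-correlation gate ->
## univariate fits -> bivariate fits -> covariate-adjusted refits -> report.

#' Pipeline configuration
#'
#' @param input path to a cohort CSV (see [read_cohort()]), or `NULL` when
#'   `cohort` or `gen_spec` is supplied.
#' @param cohort an in-memory `twin_cohort` (takes precedence over `input`).
#' @param gen_spec a [bivariate_gen_spec()] used to simulate the cohort when
#'   no input is given; defaults (via [default_study_spec()]) to the
#'   best-fitting published solution for bullying victimization and paranoia.
#' @param exposure exposure trait name.
#' @param outcomes character vector of outcome trait names (at least one).
#' @param covariates optional covariate names for adjusted bivariate refits.
#' @param gate_threshold phenotypic-correlation gate in `(0, 1)`; only
#'   outcomes correlating more strongly than this with the exposure enter
#'   bivariate modelling. Default 0.25.
#' @param transform apply the square-root transform during preprocessing
#'   (`TRUE` for raw non-negative scale totals, `FALSE` for already
#'   continuous values).
#' @param seed master seed; every downstream random step derives from it.
#' @param out_dir optional output directory for the serialized report.
#' @param n_starts_uni,n_starts_biv optimizer starts per family.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, cohort = NULL, gen_spec = NULL,
                            exposure, outcomes, covariates = character(0),
                            gate_threshold = 0.25, transform = FALSE,
                            seed = 1, out_dir = NULL,
                            n_starts_uni = 8, n_starts_biv = 4) {
  check_that(length(exposure) == 1 && length(outcomes) >= 1,
             "config needs one exposure and at least one outcome")
  check_that(gate_threshold > 0 && gate_threshold < 1,
             "gate_threshold must lie in (0, 1)")
  structure(list(input = input, cohort = cohort, gen_spec = gen_spec,
                 exposure = exposure, outcomes = outcomes,
                 covariates = covariates, gate_threshold = gate_threshold,
                 transform = transform, seed = seed, out_dir = out_dir,
                 n_starts_uni = n_starts_uni, n_starts_biv = n_starts_biv),
            class = "pipeline_config")
}

#' Default bivariate study specification
#'
#' The generating conditions used for the package's default synthetic
#' cohort: the published best-fitting bivariate solution for bullying
#' victimization (a2 = .35, c2 = .26, e2 = .39) and paranoia
#' (a2 = .52, c2 = 0, e2 = .48) with genetic correlation .55 and unique
#' environment correlation .04 (common-environment correlation dropped),
#' at 1418 MZ and 1258 DZ pairs.
#'
#' @param seed integer seed.
#' @param missing_rate element-wise MCAR rate (default 0.15, emulating
#'   questionnaire non-response).
#' @return a [bivariate_gen_spec()].
#' @export
default_study_spec <- function(seed = 1, missing_rate = 0.15) {
  bivariate_gen_spec(
    a2_x = 0.35, c2_x = 0.26, e2_x = 0.39,
    a2_y = 0.52, c2_y = 0.00, e2_y = 0.48,
    r_a = 0.55, r_c = 0, r_e = 0.04,
    n_mz = 1418, n_dz = 1258,
    missing_rate = missing_rate, seed = seed,
    trait_x = "bullying", trait_y = "paranoia")
}

#' Residualize analysis traits on covariates
#'
#' Regresses both analysis traits on the named covariates (person-level OLS,
#' both twins stacked, same machinery as the sex/age residualization),
#' re-standardizes the residuals, and returns the adjusted pair table, ready
#' for the bivariate model suite to be refit. Covariates may be per twin
#' (`<name>_1` / `<name>_2` columns) or shared per pair (`<name>`).
#'
#' @param pairs pair table with preprocessed trait values.
#' @param traits character vector of trait names to adjust.
#' @param covariates character vector of covariate names.
#' @return the adjusted pair table.
#' @export
adjust_for_covariate <- function(pairs, traits, covariates) {
  df <- as.data.frame(pairs)
  n <- nrow(df)
  covs <- lapply(covariates, function(cv) {
    if (all(paste0(cv, "_", 1:2) %in% names(df))) {
      c(df[[paste0(cv, "_1")]], df[[paste0(cv, "_2")]])
    } else if (cv %in% names(df)) {
      rep(df[[cv]], 2)
    } else {
      stop(sprintf("covariate '%s' not found in pair table", cv),
           call. = FALSE)
    }
  })
  X <- do.call(cbind, covs)
  colnames(X) <- covariates
  frac_missing <- mean(!stats::complete.cases(X))
  if (frac_missing > 0.5) {
    stop(sprintf("covariates missing for %.0f%% of persons (more than 50%%)",
                 100 * frac_missing), call. = FALSE)
  }
  for (tr in traits) {
    cols <- paste0(tr, "_", 1:2)
    y <- c(df[[cols[1]]], df[[cols[2]]])
    res <- ols_residualize(y, X)
    df[[cols[1]]] <- res[seq_len(n)]
    df[[cols[2]]] <- res[n + seq_len(n)]
  }
  finish_cohort(df, attr(pairs, "traits") %||% cohort_traits(df),
                attr(pairs, "gen_spec"))
}

## OLS residuals of y on (intercept, X), standardized over non-missing rows.
ols_residualize <- function(y, X) {
  Xf <- cbind(1, X)
  ok <- !is.na(y) & stats::complete.cases(Xf)
  check_that(sum(ok) >= ncol(Xf) + 1, "too few complete rows to residualize")
  fit <- stats::lm.fit(Xf[ok, , drop = FALSE], y[ok])
  out <- rep(NA_real_, length(y))
  out[ok] <- (fit$residuals - mean(fit$residuals)) / stats::sd(fit$residuals)
  out
}

#' Run the full study pipeline
#'
#' Executes the analysis stages in the study's order on a cohort table
#' (loaded, supplied, or simulated from `gen_spec`):
#' \enumerate{
#'   \item preprocessing of every trait (optional square-root transform,
#'     then sex/age residualization and standardization);
#'   \item descriptive statistics per trait and phenotypic correlations of
#'     the exposure with every outcome on one random member per pair;
#'   \item the correlation gate — only outcomes with `r > gate_threshold`
#'     enter bivariate modelling (an empty gate is reported, not an error);
#'   \item univariate model suite (saturated, ACE, AE, CE) with comparison
#'     table and best-model selection for the exposure and all outcomes;
#'   \item bivariate model suite (saturated, ACE, both dropped-correlation
#'     variants, AE, CE) for each gated outcome, with derived bivariate
#'     heritability and factor correlations from the best model;
#'   \item covariate-adjusted bivariate refits when covariates are named.
#' }
#' Every random step is seeded from `config$seed`; rerunning the same
#' configuration reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return a `study_report` list with blocks `descriptives`,
#'   `phenotypic_correlations`, `gate`, `univariate`, `bivariate`,
#'   `adjusted`, `log` and `provenance`. Written to `config$out_dir` as JSON
#'   and TSV when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ## stage 0: obtain the cohort
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    say("cohort: supplied in memory (%d pairs)", nrow(cohort))
  } else if (!is.null(config$input)) {
    cohort <- read_cohort(config$input)
    say("cohort: read %d pairs from %s", nrow(cohort), config$input)
  } else {
    spec <- config$gen_spec %||% default_study_spec(seed = config$seed)
    cohort <- simulate_bivariate(spec)
    say("cohort: simulated %d MZ + %d DZ pairs", spec$n_mz, spec$n_dz)
  }
  traits <- unique(c(config$exposure, config$outcomes))
  check_that(all(traits %in% cohort_traits(as.data.frame(cohort))),
             "exposure/outcome traits must be present in the cohort")

  ## stage 1: preprocessing
  processed <- cohort
  for (tr in traits) {
    processed <- preprocess_trait(processed, tr, transform = config$transform)
  }
  say("preprocess: %d traits transformed/residualized over %d families",
      length(traits), nrow(processed))

  ## stage 2: descriptives + phenotypic correlations
  desc <- lapply(traits, function(tr) {
    describe_scale(cohort, tr, transformed = processed,
                   seed = config$seed + 1)
  })
  names(desc) <- traits
  person <- select_random_member(processed, seed = config$seed + 1)
  phen <- lapply(config$outcomes, function(out_tr) {
    pearson_ci(person[[config$exposure]], person[[out_tr]])
  })
  names(phen) <- config$outcomes
  for (out_tr in config$outcomes) {
    say("phenotypic r(%s, %s) = %.3f (n = %d)", config$exposure, out_tr,
        phen[[out_tr]]$r, phen[[out_tr]]$n)
  }

  ## stage 3: gate
  gated <- correlation_gate(phen, config$gate_threshold)
  say("gate (> %.2f): %s", config$gate_threshold,
      if (length(gated)) paste(gated, collapse = ", ") else "none passed")

  ## stage 4: univariate suites
  univariate <- lapply(traits, function(tr) {
    suite <- fit_univariate_suite(processed, tr,
                                  n_starts = config$n_starts_uni,
                                  seed = config$seed + 2)
    say("univariate %s: best model %s (a2 = %.2f)", tr, suite$best,
        suite$fits[[suite$best]]$estimates$a2)
    suite
  })
  names(univariate) <- traits

  ## stage 5: bivariate suites for gated outcomes
  bivariate <- lapply(gated, function(out_tr) {
    suite <- fit_bivariate_suite(processed, c(config$exposure, out_tr),
                                 n_starts = config$n_starts_biv,
                                 seed = config$seed + 3)
    say("bivariate %s-%s: best model %s", config$exposure, out_tr,
        suite$best)
    suite
  })
  names(bivariate) <- gated

  ## stage 6: covariate-adjusted refits
  adjusted <- list()
  if (length(config$covariates) > 0 && length(gated) > 0) {
    for (out_tr in gated) {
      adj_pairs <- adjust_for_covariate(processed,
                                        c(config$exposure, out_tr),
                                        config$covariates)
      adjusted[[out_tr]] <- fit_bivariate_suite(
        adj_pairs, c(config$exposure, out_tr),
        n_starts = config$n_starts_biv, seed = config$seed + 4)
      say("adjusted bivariate %s-%s (controlling %s): best model %s",
          config$exposure, out_tr,
          paste(config$covariates, collapse = "+"),
          adjusted[[out_tr]]$best)
    }
  }

  report <- structure(list(
    descriptives = desc,
    phenotypic_correlations = phen,
    gate = list(threshold = config$gate_threshold, passed = gated),
    univariate = univariate,
    bivariate = bivariate,
    adjusted = adjusted,
    log = log_lines,
    provenance = list(
      seed = config$seed,
      exposure = config$exposure, outcomes = config$outcomes,
      covariates = config$covariates,
      gate_threshold = config$gate_threshold,
      package_version = as.character(utils::packageVersion("twinace")))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Fit the univariate model suite
#'
#' Saturated, ACE, AE and CE fits for one trait, with the comparison table
#' and the selected best model.
#'
#' @param pairs preprocessed pair table.
#' @param trait trait name.
#' @param n_starts optimizer starts.
#' @param seed seed for start jitter.
#' @return list with `fits`, `comparison`, `best`.
#' @export
fit_univariate_suite <- function(pairs, trait, n_starts = 8, seed = NULL) {
  sat <- fit_model(pairs, trait, "saturated", n_starts = n_starts, seed = seed)
  fits <- lapply(c(ACE = "ACE", AE = "AE", CE = "CE"), function(fam) {
    fit_model(pairs, trait, fam, n_starts = n_starts, seed = seed)
  })
  comparison <- compare_models(fits, sat)
  list(fits = c(list(saturated = sat), fits), comparison = comparison,
       best = select_best_model(comparison))
}

#' Fit the bivariate model suite
#'
#' Saturated, full ACE, both dropped-correlation variants, AE and CE fits
#' for a trait pair, with the comparison table, the selected best model and
#' the derived bivariate quantities from the best model's estimates. If the
#' best model's implied phenotypic correlation is (near-)zero the derived
#' shares are reported as `NULL` with `degenerate = TRUE`.
#'
#' @param pairs preprocessed pair table.
#' @param traits length-2 character vector (exposure, outcome).
#' @param n_starts optimizer starts.
#' @param seed seed for start jitter.
#' @return list with `fits`, `comparison`, `best`, `derived`, `degenerate`.
#' @export
fit_bivariate_suite <- function(pairs, traits, n_starts = 4, seed = NULL) {
  sat <- fit_model(pairs, traits, "saturated", n_starts = n_starts, seed = seed)
  fams <- c(ACE = "ACE", ACE_drop_ra = "ACE_drop_ra",
            ACE_drop_rc = "ACE_drop_rc", AE = "AE", CE = "CE")
  fits <- lapply(fams, function(fam) {
    fit_model(pairs, traits, fam, n_starts = n_starts, seed = seed)
  })
  comparison <- compare_models(fits, sat)
  best <- select_best_model(comparison)
  derived <- tryCatch(derived_bivariate(fits[[best]]$estimates),
                      error = function(e) NULL)
  degenerate <- is.null(derived) || abs(derived$r_implied) < 0.01
  list(fits = c(list(saturated = sat), fits), comparison = comparison,
       best = best, derived = derived, degenerate = degenerate)
}

#' Serialize a study report
#'
#' Writes the report as a single JSON file (`report.json`) plus TSV files
#' for every model-comparison table (`univariate_<trait>.tsv`,
#' `bivariate_<outcome>.tsv`, `adjusted_<outcome>.tsv`). Files are written
#' atomically (temp file then rename).
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  slim <- report_for_json(report)
  atomically(file.path(dir, "report.json"), function(p) {
    jsonlite::write_json(slim, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })
  write_cmp <- function(cmp, path) {
    atomically(path, function(p) {
      utils::write.table(as.data.frame(cmp), p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    })
  }
  for (tr in names(report$univariate)) {
    write_cmp(report$univariate[[tr]]$comparison,
              file.path(dir, paste0("univariate_", tr, ".tsv")))
  }
  for (tr in names(report$bivariate)) {
    write_cmp(report$bivariate[[tr]]$comparison,
              file.path(dir, paste0("bivariate_", tr, ".tsv")))
  }
  for (tr in names(report$adjusted)) {
    write_cmp(report$adjusted[[tr]]$comparison,
              file.path(dir, paste0("adjusted_", tr, ".tsv")))
  }
  invisible(dir)
}

## JSON-friendly view of the report: drop fit-internal data (sufficient
## statistics, theta vectors), keep every reported number and n.
report_for_json <- function(report) {
  suite_slim <- function(suite) {
    list(comparison = as.data.frame(suite$comparison),
         best = suite$best,
         estimates = lapply(suite$fits, function(f) {
           if (f$model == "saturated") {
             list(model = "saturated", minus2LL = f$minus2LL, df = f$df,
                  n_used = as.list(f$n_used))
           } else {
             est <- unclass(f$estimates)
             keep <- intersect(names(est),
                               c("a2", "c2", "e2", "mu",
                                 "a2_x", "c2_x", "e2_x",
                                 "a2_y", "c2_y", "e2_y",
                                 "r_a", "r_c", "r_e", "mu_x", "mu_y"))
             c(list(model = f$model, minus2LL = f$minus2LL, df = f$df,
                    converged = f$converged, boundary = f$boundary,
                    n_used = as.list(f$n_used)),
               est[keep])
           }
         }),
         derived = suite$derived, degenerate = suite$degenerate)
  }
  list(
    descriptives = lapply(report$descriptives, unclass),
    phenotypic_correlations = lapply(report$phenotypic_correlations, unclass),
    gate = report$gate,
    univariate = lapply(report$univariate, suite_slim),
    bivariate = lapply(report$bivariate, suite_slim),
    adjusted = lapply(report$adjusted, suite_slim),
    log = report$log,
    provenance = report$provenance)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads the fields of [pipeline_config()] from a `.yaml`/`.yml` or `.json`
#' file.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  check_that(length(unknown) == 0,
             paste("unknown config fields:", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}
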