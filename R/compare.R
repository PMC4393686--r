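## Model comparison against the saturated reference, closed-form Falconer
## moment estimators, and quantities derived from a bivariate solution.

#' Compare fitted models to the saturated model
#'
#' Builds the standard twin-modelling comparison table: for each fitted
#' model, the likelihood-ratio statistic against the saturated model
#' `LRT = -2LL(model) - (-2LL(saturated))`, the difference in degrees of
#' freedom, the chi-square p-value, and the Mx-convention Bayesian
#' Information Criterion `BIC = -2LL - df * log(N)` (lower / more negative
#' is better). Only BIC differences and orderings are meaningful, not
#' absolute values.
#'
#' @param fits list of `ace_fit` objects (nested in the saturated model and
#'   fitted to the same data).
#' @param saturated the saturated `ace_fit` on the same data.
#' @param n_for_bic sample size `N` in the BIC penalty; defaults to the
#'   number of twin pairs contributing to the saturated fit.
#' @return a `model_comparison` data frame with one row per model (the
#'   saturated row first), columns `model`, `minus2LL`, `df`, `LRT`,
#'   `delta_df`, `p`, `BIC`.
#' @export
compare_models <- function(fits, saturated, n_for_bic = NULL) {
  if (inherits(fits, "ace_fit")) fits <- list(fits)
  n_for_bic <- n_for_bic %||% sum(saturated$n_used)
  rows <- lapply(fits, function(f) {
    lrt <- f$minus2LL - saturated$minus2LL
    if (lrt < -1e-6) {
      stop(sprintf(
        "model '%s' fits better than the saturated model (LRT = %.3g); %s",
        f$model, lrt, "this indicates an optimizer failure"), call. = FALSE)
    }
    lrt <- max(lrt, 0)
    ddf <- f$df - saturated$df
    data.frame(model = f$model, minus2LL = f$minus2LL, df = f$df,
               LRT = lrt, delta_df = ddf,
               p = if (ddf > 0) stats::pchisq(lrt, ddf, lower.tail = FALSE)
                   else if (lrt <= 1e-12) 1 else NA_real_,
               BIC = f$minus2LL - f$df * log(n_for_bic),
               stringsAsFactors = FALSE)
  })
  sat_row <- data.frame(model = "saturated", minus2LL = saturated$minus2LL,
                        df = saturated$df, LRT = NA_real_,
                        delta_df = NA_real_, p = NA_real_,
                        BIC = saturated$minus2LL - saturated$df * log(n_for_bic),
                        stringsAsFactors = FALSE)
  out <- rbind(sat_row, do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Select the best-fitting model from a comparison table
#'
#' Selection rule: among models not rejected by the likelihood-ratio test
#' against the saturated model at level `alpha`, pick the one with the
#' lowest (most negative) BIC; ties are broken in favour of fewer free
#' parameters (larger `df`). If every model is rejected, the lowest-BIC
#' model is returned with a warning.
#'
#' @param comparison a `model_comparison` from [compare_models()].
#' @param alpha LRT rejection level (default 0.05).
#' @return the name of the selected model (character).
#' @export
select_best_model <- function(comparison, alpha = 0.05) {
  rows <- comparison[comparison$model != "saturated", , drop = FALSE]
  check_that(nrow(rows) > 0, "no candidate models in comparison")
  ok <- !is.na(rows$p) & rows$p >= alpha
  if (!any(ok)) {
    warning("every model is rejected against the saturated model; ",
            "returning the lowest-BIC model")
    ok <- rep(TRUE, nrow(rows))
  }
  cand <- rows[ok, , drop = FALSE]
  cand <- cand[order(cand$BIC, -cand$df), , drop = FALSE]
  cand$model[1]
}

#' Falconer closed-form univariate estimates
#'
#' Moment estimators from zygosity-specific twin correlations:
#' `a2 = 2 (r_MZ - r_DZ)`, `c2 = 2 r_DZ - r_MZ`, `e2 = 1 - r_MZ`.
#' No truncation is applied — estimates may fall outside `[0, 1]` and it is
#' the caller's decision what to do then. Used both as a quick descriptive
#' estimator and as the analytic oracle for the ML engine on just-identified
#' data.
#'
#' @param icc_mz,icc_dz intraclass correlations per zygosity, in `[-1, 1]`.
#' @return named numeric vector `(a2, c2, e2)`.
#' @export
falconer_univariate <- function(icc_mz, icc_dz) {
  check_that(abs(icc_mz) <= 1 && abs(icc_dz) <= 1,
             "correlations must lie in [-1, 1]")
  c(a2 = 2 * (icc_mz - icc_dz), c2 = 2 * icc_dz - icc_mz, e2 = 1 - icc_mz)
}

#' Falconer-style decomposition of a phenotypic correlation
#'
#' Applies the Falconer arithmetic to cross-twin cross-trait correlations:
#' `a_cov = 2 (CTCT_MZ - CTCT_DZ)`, `c_cov = 2 CTCT_DZ - CTCT_MZ`, and
#' `e_cov = r_phenotypic - a_cov - c_cov`, so the three parts sum to the
#' phenotypic correlation.
#'
#' @param ctct_mz,ctct_dz cross-twin cross-trait correlations per zygosity.
#' @param r_phenotypic phenotypic (within-person) cross-trait correlation.
#' @return named numeric vector `(a_cov, c_cov, e_cov)`.
#' @export
falconer_bivariate <- function(ctct_mz, ctct_dz, r_phenotypic) {
  check_that(all(abs(c(ctct_mz, ctct_dz, r_phenotypic)) <= 1),
             "correlations must lie in [-1, 1]")
  a_cov <- 2 * (ctct_mz - ctct_dz)
  c_cov <- 2 * ctct_dz - ctct_mz
  c(a_cov = a_cov, c_cov = c_cov, e_cov = r_phenotypic - a_cov - c_cov)
}

#' Quantities derived from a bivariate ACE solution
#'
#' Decomposes the model-implied phenotypic correlation into its genetic and
#' environmental parts. With standardized per-trait components, the
#' cross-trait covariance splits into `A = a_x a_y r_a`, `C = c_x c_y r_c`
#' and `E = e_x e_y r_e`; the implied phenotypic correlation is their sum,
#' and the bivariate heritability `biva2 = A / (A + C + E)` is the share of
#' the phenotypic correlation explained by genetic overlap (`bivc2`, `bive2`
#' analogously). Also returns the model-implied within-pair (intraclass)
#' correlations per zygosity and trait.
#'
#' @param params a [bivariate_ace_params()] (typically with unit-variance
#'   paths, e.g. from printed standardized estimates).
#' @return list with `biva2`, `bivc2`, `bive2`, `r_implied`, `cov_parts`
#'   (the additive/common/unique covariance contributions) and
#'   `icc_implied` (per zygosity, per trait).
#' @export
derived_bivariate <- function(params) {
  p <- params
  ## correlations a model dropped are reported as NA in fits; they
  ## contribute nothing to the covariance
  for (nm in c("r_a", "r_c", "r_e")) {
    if (is.null(p[[nm]]) || is.na(p[[nm]])) p[[nm]] <- 0
  }
  A <- p$a_x * p$a_y * p$r_a
  C <- p$c_x * p$c_y * p$r_c
  E <- p$e_x * p$e_y * p$r_e
  sd_x <- sqrt(p$a_x^2 + p$c_x^2 + p$e_x^2)
  sd_y <- sqrt(p$a_y^2 + p$c_y^2 + p$e_y^2)
  r_implied <- (A + C + E) / (sd_x * sd_y)
  total <- A + C + E
  if (abs(total) < 1e-12) {
    stop("implied phenotypic correlation is zero; bivariate shares undefined",
         call. = FALSE)
  }
  icc <- lapply(c(MZ = "MZ", DZ = "DZ"), function(zyg) {
    al <- zyg_alpha(zyg)
    c(x = (al * p$a_x^2 + p$c_x^2) / sd_x^2,
      y = (al * p$a_y^2 + p$c_y^2) / sd_y^2)
  })
  list(biva2 = A / total, bivc2 = C / total, bive2 = E / total,
       r_implied = r_implied,
       cov_parts = c(A = A, C = C, E = E),
       icc_implied = icc)
}
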