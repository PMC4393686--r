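## Profile-likelihood confidence intervals.
##
## A 95% bound for a parameter t is where the profile -2LL — the -2LL
## re-minimized over all OTHER free parameters with t held fixed — rises by
## qchisq(.95, 1) = 3.841 above its minimum. Bounds are searched within the
## parameter's domain; a profile that never crosses the threshold before the
## domain edge reports the edge itself, flagged (the analogue of printed
## interval ends like 0.00 or 1.00).

#' Profile-likelihood confidence interval for a fitted parameter
#'
#' Supported parameters: the standardized variance components `"a2"`,
#' `"c2"`, `"e2"` of a univariate ACE-family fit (domain `[0, 1]`; the
#' remaining components are re-optimized under the constraint), and the
#' factor correlations `"r_a"`, `"r_c"`, `"r_e"` of a bivariate fit (domain
#' `[-1, 1]`). Asking for a parameter the model does not estimate (e.g.
#' `"c2"` in an AE fit, or a dropped correlation) is an error.
#'
#' @param fit an `ace_fit` from [fit_model()] (must have converged).
#' @param parameter parameter name (see Details).
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `lower_at_edge`, `upper_at_edge`,
#'   `estimate` and `level`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  check_that(isTRUE(fit$converged), "profile_ci requires a converged fit")
  crit <- stats::qchisq(level, df = 1)
  if (fit$kind == "univariate") {
    profile_ci_uni(fit, parameter, crit, level)
  } else {
    profile_ci_biv(fit, parameter, crit, level)
  }
}

## --- univariate standardized components ------------------------------------

## Constrained profile for a standardized component t: parameterize the
## model as total variance V (log scale), component shares (t fixed; the
## remainder split by a logistic fraction when two other components exist)
## and the grand mean, then minimize -2LL over the free inner parameters.
profile_ci_uni <- function(fit, parameter, crit, level) {
  check_that(fit$model != "saturated",
             "profile_ci applies to ACE-family fits, not the saturated model")
  comp_names <- paste0(uni_free_paths(fit$model), "2")
  if (!parameter %in% comp_names) {
    stop(sprintf("'%s' is not a free parameter of the %s model",
                 parameter, fit$model), call. = FALSE)
  }
  others <- setdiff(comp_names, parameter)
  data <- fit$data
  est <- fit$estimates[[parameter]]

  prof <- function(t) {
    inner <- function(psi) {
      V <- exp(psi[1])
      mu <- psi[2]
      frac <- if (length(others) == 2) stats::plogis(psi[3]) else 1
      comps <- stats::setNames(numeric(3), c("a2", "c2", "e2"))
      comps[parameter] <- t
      if (length(others) >= 1) comps[others[1]] <- (1 - t) * frac
      if (length(others) == 2) comps[others[2]] <- (1 - t) * (1 - frac)
      paths <- sqrt(V * comps)
      s_mz <- uni_sigma(list(a = paths[["a2"]], c = paths[["c2"]],
                             e = paths[["e2"]]), "MZ")
      s_dz <- uni_sigma(list(a = paths[["a2"]], c = paths[["c2"]],
                             e = paths[["e2"]]), "DZ")
      fiml_neg2ll_safe(data$MZ$prep, rep(mu, 2), s_mz) +
        fiml_neg2ll_safe(data$DZ$prep, rep(mu, 2), s_dz)
    }
    start <- c(log(fit$estimates$var), fit$estimates$mu)
    if (length(others) == 2) {
      o1 <- fit$estimates[[others[1]]]
      o2 <- fit$estimates[[others[2]]]
      frac0 <- if (o1 + o2 > 1e-8) o1 / (o1 + o2) else 0.5
      start <- c(start, stats::qlogis(min(max(frac0, 1e-4), 1 - 1e-4)))
    }
    stats::optim(start, inner, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value
  }
  profile_bounds(prof, est, fit$minus2LL, crit, level,
                 domain = c(0, 1), eps = 1e-6)
}

## --- bivariate factor correlations ------------------------------------------

profile_ci_biv <- function(fit, parameter, crit, level) {
  check_that(fit$model != "saturated",
             "profile_ci applies to ACE-family fits, not the saturated model")
  fp <- biv_free_params(fit$model)
  if (!parameter %in% fp$cors) {
    stop(sprintf("'%s' is not a free parameter of the %s model",
                 parameter, fit$model), call. = FALSE)
  }
  data <- fit$data
  est <- fit$estimates[[parameter]]
  ## refit with the target correlation fixed: drop its atanh coordinate from
  ## theta by optimizing the reduced vector and injecting the fixed value
  idx <- 2 + length(fp$paths) + match(parameter, fp$cors)
  obj_full <- biv_objective(data, fit$model)
  prof <- function(r) {
    inner <- function(psi) {
      theta <- append(psi, atanh(r), after = idx - 1)
      obj_full(theta)
    }
    start <- fit$theta[-idx]
    stats::optim(start, inner, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))$value
  }
  profile_bounds(prof, est, fit$minus2LL, crit, level,
                 domain = c(-1, 1), eps = 1e-4)
}

## Search the two threshold crossings of a profile function around the
## estimate, respecting the parameter domain.
profile_bounds <- function(prof, est, min2ll, crit, level, domain, eps) {
  threshold <- min2ll + crit
  f <- function(t) prof(t) - threshold
  lo_edge <- domain[1] + eps
  hi_edge <- domain[2] - eps
  est_in <- min(max(est, lo_edge + eps), hi_edge - eps)

  lower_at_edge <- FALSE
  if (f(lo_edge) <= 0) {
    lower <- domain[1]
    lower_at_edge <- TRUE
  } else {
    lower <- stats::uniroot(f, c(lo_edge, est_in), tol = 1e-6)$root
  }
  upper_at_edge <- FALSE
  if (f(hi_edge) <= 0) {
    upper <- domain[2]
    upper_at_edge <- TRUE
  } else {
    upper <- stats::uniroot(f, c(est_in, hi_edge), tol = 1e-6)$root
  }
  list(lower = lower, upper = upper,
       lower_at_edge = lower_at_edge, upper_at_edge = upper_at_edge,
       estimate = est, level = level)
}
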