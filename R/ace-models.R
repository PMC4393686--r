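## Expected twin covariance structures and maximum-likelihood model fitting
## for the classical twin design.
##
## Parameterization: path coefficients a, c, e (sign-unconstrained reals);
## reported components are squared and standardized, a2 = a^2/(a^2+c^2+e^2)
## etc., which avoids boundary pathologies during optimization. Cross-trait
## factor correlations are optimized through atanh/tanh so they stay inside
## (-1, 1); solutions at the edge of the parameter space are flagged.

#' Univariate ACE parameters
#'
#' @param a,c,e path coefficients (any sign; components are their squares).
#' @param mu trait mean.
#' @return a `univariate_ace_params` list carrying the paths, the mean and
#'   the standardized components `a2`, `c2`, `e2`.
#' @export
univariate_ace_params <- function(a, c = 0, e, mu = 0) {
  v <- a^2 + c^2 + e^2
  check_that(v > 0, "total variance a^2 + c^2 + e^2 must be positive")
  structure(list(a = a, c = c, e = e, mu = mu, var = v,
                 a2 = a^2 / v, c2 = c^2 / v, e2 = e^2 / v),
            class = "univariate_ace_params")
}

#' Bivariate (correlated-factors) ACE parameters
#'
#' Per-trait A/C/E paths plus factor correlations `r_a`, `r_c`, `r_e`
#' between the two traits' genetic, common-environment and
#' unique-environment factors.
#'
#' @param a_x,c_x,e_x,a_y,c_y,e_y path coefficients.
#' @param r_a,r_c,r_e factor correlations in `[-1, 1]`.
#' @param mu_x,mu_y trait means.
#' @return a `bivariate_ace_params` list.
#' @export
bivariate_ace_params <- function(a_x, c_x = 0, e_x, a_y, c_y = 0, e_y,
                                 r_a = 0, r_c = 0, r_e = 0,
                                 mu_x = 0, mu_y = 0) {
  for (nm in c("r_a", "r_c", "r_e")) {
    check_that(abs(get(nm)) <= 1, sprintf("%s must lie in [-1, 1]", nm))
  }
  v_x <- a_x^2 + c_x^2 + e_x^2
  v_y <- a_y^2 + c_y^2 + e_y^2
  check_that(v_x > 0 && v_y > 0, "each trait needs positive total variance")
  structure(list(a_x = a_x, c_x = c_x, e_x = e_x,
                 a_y = a_y, c_y = c_y, e_y = e_y,
                 r_a = r_a, r_c = r_c, r_e = r_e,
                 mu_x = mu_x, mu_y = mu_y, var_x = v_x, var_y = v_y,
                 a2_x = a_x^2 / v_x, c2_x = c_x^2 / v_x, e2_x = e_x^2 / v_x,
                 a2_y = a_y^2 / v_y, c2_y = c_y^2 / v_y, e2_y = e_y^2 / v_y),
            class = "bivariate_ace_params")
}

zyg_alpha <- function(zygosity) {
  check_that(zygosity %in% c("MZ", "DZ"), "zygosity must be 'MZ' or 'DZ'")
  if (zygosity == "MZ") 1 else 0.5
}

#' Expected twin-pair covariance under a univariate ACE model
#'
#' 2x2 covariance of a trait across co-twins: diagonal `a^2 + c^2 + e^2`,
#' off-diagonal `a^2 + c^2` for MZ pairs (who share all segregating genetic
#' variants) or `0.5 a^2 + c^2` for DZ pairs (who share half on average).
#'
#' @param params a [univariate_ace_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return symmetric 2x2 matrix.
#' @export
expected_cov_univariate <- function(params, zygosity) {
  al <- zyg_alpha(zygosity)
  v <- params$a^2 + params$c^2 + params$e^2
  cv <- al * params$a^2 + params$c^2
  matrix(c(v, cv, cv, v), 2, 2)
}

#' Expected twin-pair covariance under a bivariate ACE model
#'
#' 4x4 covariance in variable order (X1, Y1, X2, Y2). Within-person
#' cross-trait covariance is `a_x a_y r_a + c_x c_y r_c + e_x e_y r_e`;
#' cross-twin same-trait entries follow the univariate structure; cross-twin
#' cross-trait entries are `alpha a_x a_y r_a + c_x c_y r_c` with
#' `alpha = 1` (MZ) or `0.5` (DZ).
#'
#' @param params a [bivariate_ace_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return symmetric positive-semidefinite 4x4 matrix.
#' @export
expected_cov_bivariate <- function(params, zygosity) {
  al <- zyg_alpha(zygosity)
  p <- params
  v_x <- p$a_x^2 + p$c_x^2 + p$e_x^2
  v_y <- p$a_y^2 + p$c_y^2 + p$e_y^2
  cov_xx <- al * p$a_x^2 + p$c_x^2
  cov_yy <- al * p$a_y^2 + p$c_y^2
  within <- p$a_x * p$a_y * p$r_a + p$c_x * p$c_y * p$r_c +
    p$e_x * p$e_y * p$r_e
  cross <- al * p$a_x * p$a_y * p$r_a + p$c_x * p$c_y * p$r_c
  m <- matrix(c(
    v_x,    within, cov_xx, cross,
    within, v_y,    cross,  cov_yy,
    cov_xx, cross,  v_x,    within,
    cross,  cov_yy, within, v_y), 4, 4)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf(
      "implied %s covariance is not positive semidefinite (eigenvalues: %s)",
      zygosity, paste(signif(ev, 4), collapse = ", ")), call. = FALSE)
  }
  m
}

## ---------------------------------------------------------------------------
## Model fitting

uni_families <- c("saturated", "ACE", "AE", "CE", "E")
biv_families <- c("saturated", "ACE", "ACE_drop_ra", "ACE_drop_rc", "AE", "CE")

## Paths present per univariate family.
uni_free_paths <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"), AE = c("a", "e"),
         CE = c("c", "e"), E = "e",
         stop("unknown univariate family: ", model, call. = FALSE))
}

## Free parameter names for a bivariate family: paths then atanh-correlations.
biv_free_params <- function(model) {
  paths <- switch(model,
                  ACE = , ACE_drop_ra = , ACE_drop_rc =
                    c("a_x", "c_x", "e_x", "a_y", "c_y", "e_y"),
                  AE = c("a_x", "e_x", "a_y", "e_y"),
                  CE = c("c_x", "e_x", "c_y", "e_y"),
                  stop("unknown bivariate family: ", model, call. = FALSE))
  cors <- switch(model,
                 ACE = c("r_a", "r_c", "r_e"),
                 ACE_drop_ra = c("r_c", "r_e"),
                 ACE_drop_rc = c("r_a", "r_e"),
                 AE = c("r_a", "r_e"),
                 CE = c("r_c", "r_e"))
  list(paths = paths, cors = cors)
}

## Data prep shared by the fitters: per-zygosity FIML sufficient statistics.
## Rows with every analysed value missing are dropped (with a count).
fit_data <- function(pairs, traits) {
  df <- as.data.frame(pairs)
  cols <- as.vector(vapply(traits, function(tr) paste0(tr, "_", 1:2),
                           character(2)))
  if (length(traits) == 2) {
    ## bivariate variable order (X1, Y1, X2, Y2)
    cols <- c(paste0(traits[1], "_1"), paste0(traits[2], "_1"),
              paste0(traits[1], "_2"), paste0(traits[2], "_2"))
  }
  check_that(all(cols %in% names(df)),
             paste("cohort lacks columns:",
                   paste(setdiff(cols, names(df)), collapse = ", ")))
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    Y <- as.matrix(df[df$zygosity == zyg, cols, drop = FALSE])
    empty <- rowSums(!is.na(Y)) == 0
    Y <- Y[!empty, , drop = FALSE]
    check_that(nrow(Y) > 0, sprintf("no usable %s pairs", zyg))
    out[[zyg]] <- list(prep = fiml_prepare(Y), n_pairs = nrow(Y),
                       n_dropped = sum(empty))
  }
  out$cols <- cols
  out$n_obs <- out$MZ$prep$n_obs + out$DZ$prep$n_obs
  out$n_pairs <- out$MZ$n_pairs + out$DZ$n_pairs
  out
}

multi_start <- function(objective, start, n_starts, seed, jitter_sd = 0.3) {
  runs <- with_seed(seed, {
    starts <- c(list(start), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      start + stats::rnorm(length(start), sd = jitter_sd)
    }))
    lapply(starts, function(s) {
      tryCatch(
        stats::optim(s, objective, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) list(value = Inf, convergence = 99L, par = s))
    })
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  best$converged <- is.finite(best$value) && best$convergence == 0L
  best
}

## ---- univariate ------------------------------------------------------------

uni_sigma <- function(paths, zygosity) {
  a <- paths[["a"]] %||% 0; c_ <- paths[["c"]] %||% 0; e <- paths[["e"]] %||% 0
  expected_cov_univariate(list(a = a, c = c_, e = e), zygosity)
}

uni_objective <- function(data, model) {
  free <- uni_free_paths(model)
  function(theta) {
    mu <- rep(theta[1], 2)
    paths <- as.list(theta[-1])
    names(paths) <- free
    s_mz <- uni_sigma(paths, "MZ")
    s_dz <- uni_sigma(paths, "DZ")
    fiml_neg2ll_safe(data$MZ$prep, mu, s_mz) +
      fiml_neg2ll_safe(data$DZ$prep, mu, s_dz)
  }
}

## Falconer-informed starting values from pairwise-complete double-entry ICCs.
uni_start <- function(pairs, trait, model, data) {
  df <- as.data.frame(pairs)
  iccs <- vapply(c("MZ", "DZ"), function(zyg) {
    m <- trait_matrix(df, trait, zyg)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3) return(0.3)
    stats::cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
  }, numeric(1))
  comps <- falconer_univariate(iccs[["MZ"]], iccs[["DZ"]])
  comps <- pmin(pmax(comps, 0.05), 0.9)
  comps <- comps / sum(comps)
  vals <- unlist(df[paste0(trait, "_", 1:2)])
  v <- stats::var(vals, na.rm = TRUE)
  mu <- mean(vals, na.rm = TRUE)
  free <- uni_free_paths(model)
  paths <- sqrt(v * comps[c(a = "a2", c = "c2", e = "e2")[free]])
  c(mu, unname(paths))
}

new_ace_fit <- function(kind, model, traits, data, opt, estimates, extra = list()) {
  n_free <- length(opt$par)
  structure(c(list(
    kind = kind, model = model, traits = traits,
    minus2LL = opt$value, n_free = n_free,
    df = data$n_obs - n_free,
    estimates = estimates,
    converged = isTRUE(opt$converged),
    boundary = isTRUE(extra$boundary),
    n_used = c(MZ = data$MZ$n_pairs, DZ = data$DZ$n_pairs),
    n_obs = data$n_obs,
    theta = opt$par,
    data = data), extra[setdiff(names(extra), "boundary")]),
    class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s %s model: -2LL = %.2f, df = %d (pairs: %d MZ / %d DZ)%s\n",
              x$kind, x$model, x$minus2LL, x$df,
              x$n_used[["MZ"]], x$n_used[["DZ"]],
              if (!x$converged) " [NOT CONVERGED]"
              else if (x$boundary) " [boundary]" else ""))
  if (x$kind == "univariate" && x$model != "saturated") {
    est <- x$estimates
    cat(sprintf("  standardized components: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
                est$a2, est$c2, est$e2))
  }
  if (x$kind == "bivariate" && x$model != "saturated") {
    est <- x$estimates
    cat(sprintf("  r_a = %s, r_c = %s, r_e = %s\n",
                fmt_or_dash(est$r_a), fmt_or_dash(est$r_c),
                fmt_or_dash(est$r_e)))
  }
  invisible(x)
}

fmt_or_dash <- function(v) if (is.null(v) || is.na(v)) "-" else sprintf("%.3f", v)

fit_uni_ace_family <- function(pairs, trait, model, n_starts, seed) {
  data <- fit_data(pairs, trait)
  obj <- uni_objective(data, model)
  start <- uni_start(pairs, trait, model, data)
  opt <- multi_start(obj, start, n_starts, seed)
  free <- uni_free_paths(model)
  paths <- stats::setNames(as.list(abs(opt$par[-1])), free)
  full <- list(a = paths$a %||% 0, c = paths$c %||% 0, e = paths$e %||% 0)
  params <- univariate_ace_params(full$a, full$c, full$e, mu = opt$par[1])
  comps <- c(params$a2, params$c2, params$e2)[match(free, c("a", "c", "e"))]
  boundary <- any(comps < 1e-4)
  new_ace_fit("univariate", model, trait, data, opt,
              estimates = params, extra = list(boundary = boundary))
}

fit_uni_saturated <- function(pairs, trait, n_starts, seed) {
  data <- fit_data(pairs, trait)
  total <- 0
  est <- list()
  theta_all <- numeric(0)
  converged <- TRUE
  for (zyg in c("MZ", "DZ")) {
    prep <- data[[zyg]]$prep
    complete <- length(prep$patterns) == 1 &&
      length(prep$patterns[[1]]$cols) == 2
    if (complete) {
      pat <- prep$patterns[[1]]
      mu <- pat$xbar
      sigma <- pat$scatter / pat$n      # ML covariance
      val <- fiml_neg2ll_prep(prep, mu, sigma)
      theta <- c(mu, log(sqrt(diag(sigma))),
                 atanh(sigma[1, 2] / sqrt(prod(diag(sigma)))))
    } else {
      obj <- function(th) {
        mu <- th[1:2]
        sds <- exp(th[3:4])
        r <- tanh(th[5])
        sigma <- matrix(c(sds[1]^2, r * sds[1] * sds[2],
                          r * sds[1] * sds[2], sds[2]^2), 2, 2)
        fiml_neg2ll_safe(prep, mu, sigma)
      }
      m <- colMeans_na(prep)
      start <- c(m$mu, log(pmax(sqrt(m$v), 1e-3)), atanh(min(max(m$r, -0.9), 0.9)))
      opt <- multi_start(obj, start, n_starts, seed)
      theta <- opt$par
      val <- opt$value
      converged <- converged && opt$converged
      mu <- theta[1:2]
      sds <- exp(theta[3:4]); r <- tanh(theta[5])
      sigma <- matrix(c(sds[1]^2, r * sds[1] * sds[2],
                        r * sds[1] * sds[2], sds[2]^2), 2, 2)
    }
    total <- total + val
    est[[zyg]] <- list(mu = mu, sigma = sigma)
    theta_all <- c(theta_all, theta)
  }
  opt <- list(value = total, par = theta_all, converged = converged)
  new_ace_fit("univariate", "saturated", trait, data, opt, estimates = est)
}

## Crude pairwise moments used only as saturated starting values.
colMeans_na <- function(prep) {
  n <- 0; s1 <- c(0, 0); npc <- 0; sxy <- 0; sxx <- c(0, 0); nv <- c(0, 0)
  mu <- c(0, 0); v <- c(1, 1); r <- 0.3
  tryCatch({
    allx <- list(c(), c())
    pairs_x <- c(); pairs_y <- c()
    for (pat in prep$patterns) {
      ## reconstruct approximate per-variable draws from the pattern stats
      for (j in seq_along(pat$cols)) {
        allx[[pat$cols[j]]] <- c(allx[[pat$cols[j]]],
                                 rep(pat$xbar[j], pat$n))
      }
      if (length(pat$cols) == 2) {
        npc <- npc + pat$n
        sxy <- sxy + pat$scatter[1, 2]
        sxx <- sxx + diag(pat$scatter)
      }
    }
    mu <- c(mean(allx[[1]]), mean(allx[[2]]))
    if (npc > 1 && all(sxx > 0)) {
      v <- sxx / npc
      r <- sxy / sqrt(prod(sxx))
    }
  }, error = function(e) NULL)
  list(mu = mu, v = v, r = r)
}

## ---- bivariate -------------------------------------------------------------

biv_params_from_theta <- function(theta, model) {
  fp <- biv_free_params(model)
  nms <- c("mu_x", "mu_y", fp$paths, fp$cors)
  th <- stats::setNames(as.list(theta), nms)
  get0_ <- function(nm) th[[nm]] %||% 0
  cors <- list(r_a = 0, r_c = 0, r_e = 0)
  for (rc in fp$cors) cors[[rc]] <- tanh(th[[rc]])
  bivariate_ace_params(
    a_x = get0_("a_x"), c_x = get0_("c_x"), e_x = get0_("e_x"),
    a_y = get0_("a_y"), c_y = get0_("c_y"), e_y = get0_("e_y"),
    r_a = cors$r_a, r_c = cors$r_c, r_e = cors$r_e,
    mu_x = th$mu_x, mu_y = th$mu_y)
}

biv_objective <- function(data, model, fixed = list()) {
  function(theta) {
    params <- tryCatch(biv_params_from_theta(theta, model),
                       error = function(e) NULL)
    if (is.null(params)) return(Inf)
    for (nm in names(fixed)) params[[nm]] <- fixed[[nm]]
    mu <- c(params$mu_x, params$mu_y, params$mu_x, params$mu_y)
    s_mz <- tryCatch(expected_cov_bivariate(params, "MZ"),
                     error = function(e) NULL)
    s_dz <- tryCatch(expected_cov_bivariate(params, "DZ"),
                     error = function(e) NULL)
    if (is.null(s_mz) || is.null(s_dz)) return(Inf)
    fiml_neg2ll_safe(data$MZ$prep, mu, s_mz) +
      fiml_neg2ll_safe(data$DZ$prep, mu, s_dz)
  }
}

## The likelihood only identifies path signs up to joint flips: negating one
## trait's path within a factor while negating that factor's correlation
## leaves every implied covariance unchanged. Report the canonical solution
## with non-negative paths and the correlation sign carried by the products.
canonicalize_biv <- function(params) {
  sgn <- function(v) ifelse(v < 0, -1, 1)
  bivariate_ace_params(
    a_x = abs(params$a_x), c_x = abs(params$c_x), e_x = abs(params$e_x),
    a_y = abs(params$a_y), c_y = abs(params$c_y), e_y = abs(params$e_y),
    r_a = params$r_a * sgn(params$a_x) * sgn(params$a_y),
    r_c = params$r_c * sgn(params$c_x) * sgn(params$c_y),
    r_e = params$r_e * sgn(params$e_x) * sgn(params$e_y),
    mu_x = params$mu_x, mu_y = params$mu_y)
}

## Moment-informed start: per-trait Falconer components plus CTCT-implied
## factor correlations.
biv_start <- function(pairs, traits, model) {
  df <- as.data.frame(pairs)
  comp <- lapply(traits, function(tr) {
    iccs <- vapply(c("MZ", "DZ"), function(zyg) {
      m <- trait_matrix(df, tr, zyg)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) < 3) return(0.3)
      stats::cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
    }, numeric(1))
    k <- falconer_univariate(iccs[["MZ"]], iccs[["DZ"]])
    k <- pmin(pmax(k, 0.05), 0.9)
    k / sum(k)
  })
  ctct <- tryCatch({
    tc <- twin_correlations(df, traits[1], traits[2], min_pairs = 3)
    c(mz = tc$ctct_mz$r, dz = tc$ctct_dz$r)
  }, error = function(e) c(mz = 0.1, dz = 0.05))
  rph <- tryCatch({
    x1 <- df[[paste0(traits[1], "_1")]]; y1 <- df[[paste0(traits[2], "_1")]]
    stats::cor(x1, y1, use = "pairwise.complete.obs")
  }, error = function(e) 0.2)
  fc <- falconer_bivariate(ctct[["mz"]], ctct[["dz"]], rph)
  cx <- comp[[1]]; cy <- comp[[2]]
  rstart <- function(cov_part, wx, wy) {
    d <- sqrt(wx * wy)
    if (d < 1e-6) return(0)
    min(max(cov_part / d, -0.9), 0.9)
  }
  r0 <- c(r_a = rstart(fc[["a_cov"]], cx[["a2"]], cy[["a2"]]),
          r_c = rstart(fc[["c_cov"]], cx[["c2"]], cy[["c2"]]),
          r_e = rstart(fc[["e_cov"]], cx[["e2"]], cy[["e2"]]))
  mu <- vapply(traits, function(tr) {
    mean(unlist(df[paste0(tr, "_", 1:2)]), na.rm = TRUE)
  }, numeric(1))
  vv <- vapply(traits, function(tr) {
    stats::var(unlist(df[paste0(tr, "_", 1:2)]), na.rm = TRUE)
  }, numeric(1))
  fp <- biv_free_params(model)
  path_vals <- vapply(fp$paths, function(p) {
    tr_i <- if (grepl("_x$", p)) 1 else 2
    comp_name <- paste0(substr(p, 1, 1), "2")
    sqrt(vv[tr_i] * comp[[tr_i]][[comp_name]])
  }, numeric(1))
  cor_vals <- atanh(vapply(fp$cors, function(rc) r0[[rc]], numeric(1)))
  c(unname(mu), unname(path_vals), unname(cor_vals))
}

fit_biv_ace_family <- function(pairs, traits, model, n_starts, seed,
                               fixed = list()) {
  data <- fit_data(pairs, traits)
  obj <- biv_objective(data, model, fixed)
  start <- biv_start(pairs, traits, model)
  opt <- multi_start(obj, start, n_starts, seed, jitter_sd = 0.2)
  params <- canonicalize_biv(biv_params_from_theta(opt$par, model))
  fp <- biv_free_params(model)
  est <- params
  ## absent correlations reported as NA, not 0, in the estimate view
  for (rc in setdiff(c("r_a", "r_c", "r_e"), fp$cors)) est[[rc]] <- NA_real_
  comps <- unlist(params[c("a2_x", "c2_x", "e2_x", "a2_y", "c2_y", "e2_y")])
  present <- unlist(lapply(fp$paths, function(p) {
    paste0(substr(p, 1, 1), "2_", sub("^.*_", "", p))
  }))
  boundary <- any(comps[present] < 1e-4) ||
    any(abs(unlist(params[fp$cors])) > 0.995)
  new_ace_fit("bivariate", model, traits, data, opt, estimates = est,
              extra = list(boundary = boundary, fixed = fixed))
}

fit_biv_saturated <- function(pairs, traits, n_starts, seed) {
  data <- fit_data(pairs, traits)
  total <- 0
  est <- list()
  theta_all <- numeric(0)
  converged <- TRUE
  for (zyg in c("MZ", "DZ")) {
    prep <- data[[zyg]]$prep
    complete <- length(prep$patterns) == 1 &&
      length(prep$patterns[[1]]$cols) == 4
    if (complete) {
      pat <- prep$patterns[[1]]
      mu <- pat$xbar
      sigma <- pat$scatter / pat$n
      val <- fiml_neg2ll_prep(prep, mu, sigma)
      L <- t(chol(sigma))
      theta <- c(mu, log(diag(L)), L[lower.tri(L)])
    } else {
      obj <- function(th) {
        mu <- th[1:4]
        L <- diag(exp(th[5:8]))
        L[lower.tri(L)] <- th[9:14]
        fiml_neg2ll_safe(prep, mu, tcrossprod(L))
      }
      start <- biv_sat_start(prep)
      opt <- multi_start(obj, start, n_starts, seed, jitter_sd = 0.1)
      theta <- opt$par
      val <- opt$value
      converged <- converged && opt$converged
      mu <- theta[1:4]
      L <- diag(exp(theta[5:8]))
      L[lower.tri(L)] <- theta[9:14]
      sigma <- tcrossprod(L)
    }
    total <- total + val
    est[[zyg]] <- list(mu = mu, sigma = sigma)
    theta_all <- c(theta_all, theta)
  }
  opt <- list(value = total, par = theta_all, converged = converged)
  new_ace_fit("bivariate", "saturated", traits, data, opt, estimates = est)
}

## Starting values for the 14-parameter saturated group model from
## pairwise-available moments.
biv_sat_start <- function(prep) {
  p <- prep$p
  sums <- rep(0, p); ns <- rep(0, p)
  S <- diag(p) * 0; Np <- matrix(0, p, p)
  for (pat in prep$patterns) {
    idx <- pat$cols
    sums[idx] <- sums[idx] + pat$xbar * pat$n
    ns[idx] <- ns[idx] + pat$n
    S[idx, idx] <- S[idx, idx] + pat$scatter +
      pat$n * tcrossprod(pat$xbar)
    Np[idx, idx] <- Np[idx, idx] + pat$n
  }
  mu <- ifelse(ns > 0, sums / pmax(ns, 1), 0)
  C <- S / pmax(Np, 1) - tcrossprod(mu)
  ## ridge toward a sane PSD start
  C <- C + diag(p) * max(1e-3, -min(eigen(C, symmetric = TRUE,
                                          only.values = TRUE)$values) + 1e-3)
  L <- t(chol(C))
  c(mu, log(diag(L)), L[lower.tri(L)])
}

## ---- public fitting surface ------------------------------------------------

#' Fit a twin variance-component model by FIML
#'
#' Fits a univariate (one trait) or bivariate (two traits) model to a twin
#' pair table by full-information maximum likelihood, with multi-start
#' quasi-Newton optimization. The input is expected to be preprocessed
#' (transformed, sex/age-residualized, standardized), as in the classical
#' analysis pipeline, though the likelihood itself does not require it.
#'
#' Families:
#' \describe{
#'   \item{univariate}{`"saturated"` (free means/variances/covariance per
#'     zygosity, 10 parameters), `"ACE"`, `"AE"`, `"CE"`, `"E"` (paths plus
#'     one grand mean, equated across twins and zygosities).}
#'   \item{bivariate}{`"saturated"` (free mean vector and 4x4 covariance per
#'     zygosity, 28 parameters), `"ACE"` (full correlated-factors solution,
#'     11 parameters), `"ACE_drop_ra"` / `"ACE_drop_rc"` (the genetic or
#'     common-environment factor correlation fixed to 0), `"AE"`, `"CE"`.}
#' }
#'
#' @param pairs pair table (`twin_cohort` or compatible data frame).
#' @param traits one or two trait names.
#' @param family model family (see Details).
#' @param n_starts number of optimizer starts (first start is
#'   moment-informed, the rest are jittered). Defaults to 8 for univariate
#'   and 4 for bivariate families.
#' @param seed seed for the start jitter.
#' @return an `ace_fit` with elements `minus2LL`, `df` (observed data points
#'   minus free parameters), `estimates` (fitted parameters including
#'   standardized components), `converged`, `boundary` and `n_used`.
#' @export
fit_model <- function(pairs, traits, family, n_starts = NULL, seed = NULL) {
  if (length(traits) == 1) {
    check_that(family %in% uni_families,
               paste("unknown univariate family:", family))
    n_starts <- n_starts %||% 8
    if (family == "saturated") {
      fit_uni_saturated(pairs, traits, n_starts, seed)
    } else {
      fit_uni_ace_family(pairs, traits, family, n_starts, seed)
    }
  } else if (length(traits) == 2) {
    check_that(family %in% biv_families,
               paste("unknown bivariate family:", family))
    n_starts <- n_starts %||% 4
    if (family == "saturated") {
      fit_biv_saturated(pairs, traits, n_starts, seed)
    } else {
      fit_biv_ace_family(pairs, traits, family, n_starts, seed)
    }
  } else {
    stop("traits must name one or two traits", call. = FALSE)
  }
}
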