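fake_fit <- function(model, minus2LL, df) {
  structure(list(model = model, minus2LL = minus2LL, df = df,
                 n_used = c(MZ = 0, DZ = 0)), class = "ace_fit")
}

test_that("expected univariate covariance follows the twin algebra", {
  p <- univariate_ace_params(a = 1, c = 0, e = 0)
  expect_equal(expected_cov_univariate(p, "MZ"), matrix(1, 2, 2))
  ## full-ACE paranoia solution: implied MZ correlation a2 + c2 = .52
  q <- univariate_ace_params(a = sqrt(.45), c = sqrt(.07), e = sqrt(.48))
  expect_equal(expected_cov_univariate(q, "MZ")[1, 2], .52,
               tolerance = 1e-10)
  ## DZ off-diagonal is the MZ one minus a^2/2, for any parameters
  set.seed(61)
  for (i in 1:5) {
    pp <- univariate_ace_params(a = rnorm(1), c = rnorm(1), e = runif(1, .3, 1))
    expect_equal(expected_cov_univariate(pp, "DZ")[1, 2],
                 expected_cov_univariate(pp, "MZ")[1, 2] - pp$a^2 / 2,
                 tolerance = 1e-12)
  }
  expect_error(expected_cov_univariate(q, "XX"), "zygosity")
})

test_that("expected bivariate covariance follows the correlated-factors algebra", {
  tab <- bivariate_ace_params(
    a_x = sqrt(.35), c_x = sqrt(.26), e_x = sqrt(.39),
    a_y = sqrt(.52), c_y = 0, e_y = sqrt(.48),
    r_a = .55, r_c = 0, r_e = .04)
  mz <- expected_cov_bivariate(tab, "MZ")
  dz <- expected_cov_bivariate(tab, "DZ")
  ## implied phenotypic correlation ~ .252
  expect_equal(mz[1, 2], sqrt(.35 * .52) * .55 + sqrt(.39 * .48) * .04,
               tolerance = 1e-12)
  ## MZ - DZ cross-twin cross-trait gap identifies half the genetic part
  expect_equal(mz[1, 4] - dz[1, 4], .5 * sqrt(.35) * sqrt(.52) * .55,
               tolerance = 1e-12)
  ## zero factor correlations make traits block-independent
  ind <- bivariate_ace_params(a_x = .6, c_x = .4, e_x = .6,
                              a_y = .5, c_y = .3, e_y = .7)
  m <- expected_cov_bivariate(ind, "MZ")
  expect_equal(m[1, 2], 0); expect_equal(m[1, 4], 0); expect_equal(m[2, 3], 0)
  ## tampered correlations outside [-1,1] produce a non-PSD error
  broken <- tab
  broken$r_a <- 3
  expect_error(expected_cov_bivariate(broken, "MZ"), "positive semidefinite")
})

test_that("saturated fit equals the closed-form ML moments on complete data", {
  spec <- univariate_gen_spec(a2 = .5, c2 = .2, e2 = .3, n_mz = 400,
                              n_dz = 400, seed = 62)
  co <- preprocess_trait(simulate_univariate(spec), "trait",
                         transform = FALSE)
  sat <- fit_model(co, "trait", "saturated", seed = 1)
  df <- as.data.frame(co)
  closed <- 0
  for (zyg in c("MZ", "DZ")) {
    Y <- as.matrix(df[df$zygosity == zyg, c("trait_1", "trait_2")])
    n <- nrow(Y)
    closed <- closed + fiml_neg2ll(Y, colMeans(Y), cov(Y) * (n - 1) / n)
  }
  expect_equal(sat$minus2LL, closed, tolerance = 1e-6)
  expect_equal(sat$df, 2 * 800 - 10)
})

test_that("nested models respect likelihood monotonicity and df bookkeeping", {
  pp <- bullying_cohort()
  sat <- fit_model(pp, "bully", "saturated", seed = 2)
  ace <- fit_model(pp, "bully", "ACE", seed = 2)
  ae <- fit_model(pp, "bully", "AE", seed = 2)
  ce <- fit_model(pp, "bully", "CE", seed = 2)
  e <- fit_model(pp, "bully", "E", seed = 2)
  expect_true(sat$minus2LL <= ace$minus2LL + 1e-6)
  expect_true(ace$minus2LL <= ae$minus2LL + 1e-6)
  expect_true(ace$minus2LL <= ce$minus2LL + 1e-6)
  expect_true(ce$minus2LL <= e$minus2LL + 1e-6)
  expect_true(ae$minus2LL <= e$minus2LL + 1e-6)
  cmp <- compare_models(list(ace, ae, ce), sat)
  expect_equal(cmp$delta_df[cmp$model == "ACE"], 6)
  expect_equal(cmp$delta_df[cmp$model == "AE"], 7)
  ## on strongly MZ>DZ-correlated data, dropping A hurts far more than
  ## keeping the full decomposition
  expect_gt(cmp$LRT[cmp$model == "CE"], cmp$LRT[cmp$model == "ACE"] + 10)
})

test_that("bivariate df bookkeeping reproduces the 17/18/20 deltas", {
  pp <- study_cohort()
  sat <- fit_model(pp, c("bullying", "paranoia"), "saturated", seed = 3)
  fits <- lapply(c("ACE", "ACE_drop_rc", "ACE_drop_ra", "AE"), function(f) {
    fit_model(pp, c("bullying", "paranoia"), f, seed = 3)
  })
  cmp <- compare_models(fits, sat)
  expect_equal(cmp$delta_df[cmp$model == "ACE"], 17)
  expect_equal(cmp$delta_df[cmp$model == "ACE_drop_rc"], 18)
  expect_equal(cmp$delta_df[cmp$model == "ACE_drop_ra"], 18)
  expect_equal(cmp$delta_df[cmp$model == "AE"], 20)
  expect_true(all(cmp$LRT[-1] >= -1e-6, na.rm = TRUE))
})

test_that("model comparison reproduces printed fit-statistic arithmetic", {
  sat <- fake_fit("saturated", 23507.87, 6525)
  ae <- fake_fit("AE", 23513.44, 6532)
  cmp <- compare_models(list(ae), sat, n_for_bic = 3294)
  expect_equal(cmp$LRT[2], 5.57, tolerance = 1e-9)
  expect_equal(cmp$delta_df[2], 7)
  expect_equal(cmp$p[2], pchisq(5.57, 7, lower.tail = FALSE))
  expect_gt(cmp$p[2], .55)

  ## a model compared to itself: LRT 0, p 1
  self <- compare_models(list(fake_fit("ACE", 23507.87, 6525)), sat)
  expect_equal(self$LRT[2], 0)
  expect_equal(self$p[2], 1)

  ## univariate ACE vs CE BIC difference at ln(N) = 8.101 is about -60.82
  ace <- fake_fit("ACE", 23511.61, 6531)
  ce <- fake_fit("CE", 23580.53, 6532)
  cmp2 <- compare_models(list(ace, ce), sat, n_for_bic = exp(8.101))
  bic_diff <- cmp2$BIC[cmp2$model == "ACE"] - cmp2$BIC[cmp2$model == "CE"]
  expect_equal(bic_diff, -29396.49 - (-29335.67), tolerance = .05)

  ## an optimizer failure (better fit than saturated) is an error
  expect_error(compare_models(list(fake_fit("AE", 23500, 6532)), sat),
               "optimizer")
})

test_that("the selection rule prefers low BIC among non-rejected models", {
  sat <- fake_fit("saturated", 1000, 500)
  good <- fake_fit("AE", 1003, 507)       # p large, parsimonious
  full <- fake_fit("ACE", 1002, 506)      # p large, more parameters
  bad <- fake_fit("CE", 1080, 507)        # strongly rejected
  cmp <- compare_models(list(full, good, bad), sat, n_for_bic = 1000)
  expect_equal(select_best_model(cmp), "AE")
  cmp_bad <- compare_models(list(bad), sat, n_for_bic = 1000)
  expect_warning(pick <- select_best_model(cmp_bad), "rejected")
  expect_equal(pick, "CE")
})

test_that("Falconer closed forms match hand arithmetic", {
  expect_equal(falconer_univariate(.62, .42),
               c(a2 = .40, c2 = .22, e2 = .38), tolerance = 1e-12)
  expect_equal(falconer_univariate(.5, .25),
               c(a2 = .5, c2 = 0, e2 = .5), tolerance = 1e-12)
  fb <- falconer_bivariate(.26, .12, .26)
  expect_equal(fb, c(a_cov = .28, c_cov = -.02, e_cov = .00),
               tolerance = 1e-12)
  expect_equal(sum(fb), .26, tolerance = 1e-12)
  expect_equal(falconer_bivariate(.3, .3, .4)[["a_cov"]], 0)
  expect_error(falconer_univariate(1.2, .4), "\\[-1, 1\\]")
})

test_that("FIML agrees with the Falconer oracle on moment-matched data", {
  ## data constructed so the ML sample moments are exactly the target twin
  ## correlations with unit variances and zero means: the ACE model is
  ## just-identified there and its MLE must equal the Falconer solution
  n <- 800
  mz <- moment_matched(n, c(0, 0), matrix(c(1, .62, .62, 1), 2), seed = 63)
  dz <- moment_matched(n, c(0, 0), matrix(c(1, .42, .42, 1), 2), seed = 64)
  pairs <- data.frame(
    family_id = sprintf("f%d", 1:(2 * n)),
    zygosity = rep(c("MZ", "DZ"), each = n),
    sex_1 = "female", sex_2 = "female", age = 16,
    trait_1 = c(mz[, 1], dz[, 1]), trait_2 = c(mz[, 2], dz[, 2]))
  fit <- fit_model(pairs, "trait", "ACE", seed = 4)
  target <- falconer_univariate(.62, .42)
  expect_equal(fit$estimates$a2, target[["a2"]], tolerance = 1e-4)
  expect_equal(fit$estimates$c2, target[["c2"]], tolerance = 1e-4)
  expect_equal(fit$estimates$e2, target[["e2"]], tolerance = 1e-4)
  expect_equal(fit$estimates$a2 + fit$estimates$c2 + fit$estimates$e2, 1,
               tolerance = 1e-10)
})

test_that("derived bivariate shares decompose the implied correlation", {
  tab <- bivariate_ace_params(
    a_x = sqrt(.35), c_x = sqrt(.26), e_x = sqrt(.39),
    a_y = sqrt(.52), c_y = 0, e_y = sqrt(.48),
    r_a = .55, r_c = 0, r_e = .04)
  d <- derived_bivariate(tab)
  expect_equal(d$biva2, .93, tolerance = .005)
  expect_equal(d$biva2 + d$bivc2 + d$bive2, 1, tolerance = 1e-10)
  expect_equal(d$r_implied, sum(d$cov_parts), tolerance = 1e-12)
  expect_equal(d$icc_implied$MZ[["y"]], .52, tolerance = 1e-10)

  pure <- bivariate_ace_params(a_x = .7, c_x = .3, e_x = .5,
                               a_y = .6, c_y = .2, e_y = .6,
                               r_a = .5, r_c = 0, r_e = 0)
  expect_equal(derived_bivariate(pure)$biva2, 1)
  none <- bivariate_ace_params(a_x = .7, c_x = .3, e_x = .5,
                               a_y = .6, c_y = .2, e_y = .6)
  expect_error(derived_bivariate(none), "undefined")
})

test_that("profile intervals match the Wald approximation at large n", {
  spec <- univariate_gen_spec(a2 = .5, c2 = .2, e2 = .3,
                              n_mz = 6000, n_dz = 6000, seed = 65,
                              beta_sex = 0, beta_age = 0)
  pp <- preprocess_trait(simulate_univariate(spec), "trait",
                         transform = FALSE)
  fit <- fit_model(pp, "trait", "ACE", seed = 5)
  ci <- profile_ci(fit, "a2")
  ## delta-method oracle: numeric Hessian of -2LL over (mu, a, c, e),
  ## parameter covariance 2 H^-1, then the gradient of a2 = a^2/total
  df <- as.data.frame(pp)
  ymz <- as.matrix(df[df$zygosity == "MZ", c("trait_1", "trait_2")])
  ydz <- as.matrix(df[df$zygosity == "DZ", c("trait_1", "trait_2")])
  obj <- function(th) {
    p <- univariate_ace_params(th[2], th[3], th[4], mu = th[1])
    fiml_neg2ll(ymz, rep(th[1], 2), expected_cov_univariate(p, "MZ")) +
      fiml_neg2ll(ydz, rep(th[1], 2), expected_cov_univariate(p, "DZ"))
  }
  est <- fit$estimates
  th <- c(est$mu, est$a, est$c, est$e)
  H <- pracma::hessian(obj, th)
  V <- 2 * solve(H)
  g <- pracma::grad(function(t) t[2]^2 / (t[2]^2 + t[3]^2 + t[4]^2), th)
  se <- sqrt(drop(t(g) %*% V %*% g))
  expect_equal(ci$lower, est$a2 - 1.96 * se, tolerance = .01)
  expect_equal(ci$upper, est$a2 + 1.96 * se, tolerance = .01)
  expect_false(ci$lower_at_edge || ci$upper_at_edge)
  expect_error(profile_ci(fit, "r_a"), "not a free parameter")
})

test_that("profiling a dropped parameter is rejected", {
  pp <- bullying_cohort()
  ae <- fit_model(pp, "bully", "AE", seed = 6)
  expect_error(profile_ci(ae, "c2"), "not a free parameter")
  biv <- fit_model(study_cohort(), c("bullying", "paranoia"),
                   "ACE_drop_rc", seed = 6)
  expect_error(profile_ci(biv, "r_c"), "not a free parameter")
  ci <- profile_ci(biv, "r_a")
  expect_true(ci$lower < biv$estimates$r_a &&
                biv$estimates$r_a < ci$upper)
})
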