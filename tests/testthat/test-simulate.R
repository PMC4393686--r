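test_that("generation specs validate their fields", {
  expect_error(univariate_gen_spec(a2 = .5, c2 = .6, e2 = 0,
                                   n_mz = 10, n_dz = 10),
               "sum to 1")
  expect_error(univariate_gen_spec(a2 = -.1, c2 = .5, e2 = .6,
                                   n_mz = 10, n_dz = 10),
               "a2")
  expect_error(univariate_gen_spec(a2 = .5, c2 = 0, e2 = .5,
                                   n_mz = 0, n_dz = 10),
               "n_mz")
  expect_error(univariate_gen_spec(a2 = .5, c2 = 0, e2 = .5,
                                   n_mz = 10, n_dz = 10, missing_rate = 1),
               "missing_rate")
  expect_error(bivariate_gen_spec(a2_x = .5, c2_x = .5, e2_x = .5,
                                  a2_y = .5, c2_y = 0, e2_y = .5,
                                  n_mz = 10, n_dz = 10),
               "sum to 1")
  expect_error(bivariate_gen_spec(a2_x = .5, c2_x = 0, e2_x = .5,
                                  a2_y = .5, c2_y = 0, e2_y = .5,
                                  r_a = 1.2, n_mz = 10, n_dz = 10),
               "r_a")
})

test_that("a fixed seed reproduces cohorts exactly", {
  spec <- univariate_gen_spec(a2 = .4, c2 = .2, e2 = .4, n_mz = 60, n_dz = 60,
                              missing_rate = .2, seed = 9)
  expect_identical(as.data.frame(simulate_univariate(spec)),
                   as.data.frame(simulate_univariate(spec)))
  bspec <- default_study_spec(seed = 9)
  expect_identical(as.data.frame(simulate_bivariate(bspec)),
                   as.data.frame(simulate_bivariate(bspec)))
})

test_that("pure-noise cohorts show no twin resemblance", {
  spec <- univariate_gen_spec(a2 = 0, c2 = 0, e2 = 1, n_mz = 5000,
                              n_dz = 5000, seed = 10,
                              beta_sex = 0, beta_age = 0)
  co <- simulate_univariate(spec)
  icc <- twin_correlations(co, "trait")
  mc_se <- 1 / sqrt(5000)
  expect_lt(abs(icc$icc_mz$r), 3 * mc_se)
  expect_lt(abs(icc$icc_dz$r), 3 * mc_se)
})

trait_values <- function(co, k) as.data.frame(co)[[paste0("trait_", k)]]

test_that("univariate sample moments match the ACE covariance algebra", {
  ## a2 + c2 = .61 (MZ) and .5 a2 + c2 = .435 (DZ) at the bullying solution
  spec <- univariate_gen_spec(a2 = .35, c2 = .26, e2 = .39,
                              n_mz = 20000, n_dz = 20000, seed = 11,
                              beta_sex = 0, beta_age = 0)
  co <- simulate_univariate(spec)
  icc <- twin_correlations(co, "trait")
  mc_se <- 1 / sqrt(20000)
  expect_lt(abs(icc$icc_mz$r - .61), 3 * mc_se)
  expect_lt(abs(icc$icc_dz$r - .435), 3 * mc_se)
  vals <- c(trait_values(co, 1), trait_values(co, 2))
  expect_lt(abs(var(vals) - 1), .02)
})

test_that("missingness is MCAR and never empties a pair", {
  spec <- univariate_gen_spec(a2 = .5, c2 = 0, e2 = .5, n_mz = 8000,
                              n_dz = 2000, missing_rate = .3, seed = 12,
                              beta_sex = 0, beta_age = 0)
  co <- as.data.frame(simulate_univariate(spec))
  expect_true(all(rowSums(!is.na(co[c("trait_1", "trait_2")])) >= 1))
  ## under MCAR, twin-2 values are unrelated to twin-1 missingness
  mz <- co[co$zygosity == "MZ", ]
  ok <- !is.na(mz$trait_2)
  r <- cor(as.numeric(is.na(mz$trait_1))[ok], mz$trait_2[ok])
  expect_lt(abs(r), 3 / sqrt(sum(ok)))
})

test_that("bivariate cohorts reproduce the cross-trait factor algebra", {
  ## independence when all factor correlations vanish
  spec0 <- bivariate_gen_spec(a2_x = .35, c2_x = .26, e2_x = .39,
                              a2_y = .52, c2_y = 0, e2_y = .48,
                              r_a = 0, r_c = 0, r_e = 0,
                              n_mz = 8000, n_dz = 8000, seed = 13,
                              beta_sex = 0, beta_age = 0)
  co0 <- as.data.frame(simulate_bivariate(spec0))
  expect_lt(abs(cor(co0$x_1, co0$y_1)), 3 / sqrt(nrow(co0)))

  ## published best-fit values: implied one-person phenotypic correlation
  ## sqrt(.35*.52)*.55 + sqrt(.39*.48)*.04 = .2519, and MZ cross-twin
  ## cross-trait correlation a_x a_y r_a = .2346
  spec <- bivariate_gen_spec(a2_x = .35, c2_x = .26, e2_x = .39,
                             a2_y = .52, c2_y = 0, e2_y = .48,
                             r_a = .55, r_c = 0, r_e = .04,
                             n_mz = 20000, n_dz = 20000, seed = 14,
                             beta_sex = 0, beta_age = 0)
  co <- simulate_bivariate(spec)
  person <- select_random_member(co, seed = 15)
  r_ph <- cor(person$x, person$y)
  expect_lt(abs(r_ph - (sqrt(.35 * .52) * .55 + sqrt(.39 * .48) * .04)),
            3 / sqrt(nrow(person)))
  ctct <- twin_correlations(co, "x", "y")
  expect_lt(abs(ctct$ctct_mz$r - sqrt(.35 * .52) * .55), 3 / sqrt(20000))
})

test_that("parallel items reproduce the Spearman-Brown alpha", {
  expect_equal(cronbach_alpha(simulate_items(5, 1, 200, seed = 16)), 1)
  items <- simulate_items(10, .3, 40000, seed = 17)
  expect_lt(abs(cronbach_alpha(items) - 10 * .3 / (1 + 9 * .3)), .01)
  items0 <- simulate_items(2, 0, 50000, seed = 18)
  expect_lt(abs(cronbach_alpha(items0)), .03)
  expect_error(simulate_items(1, .3, 10), "k")
})

test_that("raw-scale mapping is bounded, monotone and skew-inducing", {
  z <- rnorm(5000)
  raw <- apply_raw_scale(z, 0, 32, skew_power = 3)
  expect_true(all(raw >= 0 & raw <= 32))
  expect_gt(skewness(raw), 0.5)
  ## monotone before rounding: rank correlation exactly 1
  raw_c <- apply_raw_scale(z, 0, 32, skew_power = 3, rounding = FALSE)
  expect_equal(cor(z, raw_c, method = "spearman"), 1)
  ## degenerate constant input stays constant
  expect_length(unique(apply_raw_scale(rep(2, 5), 0, 10)), 1)
  ## missing passes through
  expect_true(is.na(apply_raw_scale(c(1, NA, 3), 0, 10)[2]))
  expect_error(apply_raw_scale(z, 5, 5), "target_min")
})
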