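test_that("moment statistics agree with an independent implementation", {
  set.seed(41)
  x <- rnorm(50000)
  expect_lt(abs(skewness(x)), .05)
  expect_lt(abs(kurtosis(x) - 3), .1)
  y <- rchisq(2000, df = 3)
  expect_equal(skewness(y), e1071::skewness(y, type = 1), tolerance = 1e-12)
  expect_equal(kurtosis(y), e1071::kurtosis(y, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("pearson_ci reproduces hand-computed and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_ci(x, x)$r, 1)
  ## rows (1,2),(2,1),(3,4),(4,3): sum of deviation products 3, both sums of
  ## squares 5, so r = 3/5 = 0.6 by the Pearson formula
  res <- pearson_ci(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  expect_equal(res$n, 4)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  expect_error(pearson_ci(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_ci(c(1, 2, NA), c(1, 2, 3)), "at least 4")
})

test_that("Fisher-z intervals for r cover the truth about 95% of the time", {
  set.seed(42)
  rho <- .26
  hits <- vapply(1:300, function(i) {
    n <- 400
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_ci(z1, z2)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gt(mean(hits), .91)
  expect_lt(mean(hits), .99)
})

test_that("two-way ANOVA block matches a brute-force sums-of-squares oracle", {
  ## 40 pairs, both twins identical so random-member selection is immaterial
  set.seed(43)
  cell <- expand.grid(sex = c("male", "female"), zyg = c("MZ", "DZ"))
  df <- do.call(rbind, lapply(seq_len(nrow(cell)), function(i) {
    y <- c(2, 3, 5, 3)[i] + rnorm(10, sd = .5)
    data.frame(family_id = sprintf("f%d_%d", i, 1:10),
               zygosity = as.character(cell$zyg[i]),
               sex_1 = as.character(cell$sex[i]),
               sex_2 = as.character(cell$sex[i]), age = 16,
               score_1 = y, score_2 = y, stringsAsFactors = FALSE)
  }))
  row <- describe_scale(df, "score", transformed = df, seed = 1)

  person <- select_random_member(df, seed = 1)
  person$sex <- factor(person$sex, levels = c("male", "female"))
  person$zygosity <- factor(person$zygosity, levels = c("MZ", "DZ"))
  rss <- function(f) sum(resid(lm(f, data = person))^2)
  rss_full <- rss(score ~ sex * zygosity)
  df_res <- nrow(person) - 4
  p_of <- function(ss, df1) {
    pf((ss / df1) / (rss_full / df_res), df1, df_res, lower.tail = FALSE)
  }
  ## type-II: each main effect adjusted for the other, interaction last
  expect_equal(row$p_sex, p_of(rss(score ~ zygosity) -
                                 rss(score ~ sex + zygosity), 1),
               tolerance = 1e-8)
  expect_equal(row$p_zyg, p_of(rss(score ~ sex) -
                                 rss(score ~ sex + zygosity), 1),
               tolerance = 1e-8)
  expect_equal(row$p_sex_zyg, p_of(rss(score ~ sex + zygosity) - rss_full, 1),
               tolerance = 1e-8)
  tss <- sum((person$score - mean(person$score))^2)
  expect_equal(row$r_squared, 1 - rss_full / tss, tolerance = 1e-8)
  expect_equal(row$n_anova, 40)
})

test_that("describe_scale reports moments, range and alpha", {
  set.seed(44)
  items <- simulate_items(10, .3, 4000, seed = 44)
  total <- rowSums(items) - min(rowSums(items))   # non-negative totals
  df <- data.frame(family_id = sprintf("f%d", 1:2000),
                   zygosity = rep(c("MZ", "DZ"), 1000),
                   sex_1 = sample(c("male", "female"), 2000, TRUE),
                   sex_2 = sample(c("male", "female"), 2000, TRUE),
                   age = runif(2000, 15, 18),
                   s_1 = total[1:2000], s_2 = total[2001:4000])
  row <- describe_scale(df, "s", items = items, seed = 2)
  expect_equal(row$alpha, 10 * .3 / (1 + 9 * .3), tolerance = .02)
  expect_equal(row$score_range, range(total))
  expect_equal(unname(row$mean_sd_total["mean"]), mean(total),
               tolerance = 1e-12)
  expect_true(row$r_squared >= 0 && row$r_squared <= 1)
})

test_that("double-entry twin correlations behave as intraclass estimators", {
  spec <- univariate_gen_spec(a2 = .45, c2 = .07, e2 = .48,
                              n_mz = 20000, n_dz = 20000, seed = 45,
                              beta_sex = 0, beta_age = 0)
  co <- simulate_univariate(spec)
  tc <- twin_correlations(co, "trait")
  ## implied MZ correlation a2 + c2 = .52
  expect_lt(abs(tc$icc_mz$r - .52), 3 / sqrt(20000))
  expect_true(tc$icc_mz$ci_low <= tc$icc_mz$r &&
                tc$icc_mz$r <= tc$icc_mz$ci_high)

  ## invariance to within-pair twin ordering
  df <- as.data.frame(co)
  set.seed(46)
  flip <- sample(c(TRUE, FALSE), nrow(df), TRUE)
  df2 <- df
  df2[flip, c("trait_1", "trait_2")] <- df[flip, c("trait_2", "trait_1")]
  tc2 <- twin_correlations(df2, "trait")
  expect_equal(tc2$icc_mz$r, tc$icc_mz$r, tolerance = 1e-12)
  expect_equal(tc2$icc_dz$r, tc$icc_dz$r, tolerance = 1e-12)

  ## duplicated trait across twins gives ICC 1
  dup <- df[c(1:50, which(df$zygosity == "DZ")[1:50]), ]
  dup$trait_2 <- dup$trait_1
  expect_equal(twin_correlations(dup, "trait")$icc_mz$r, 1)
  expect_error(twin_correlations(df[1:5, ], "trait"), "complete")
})

test_that("the correlation gate applies a strict threshold", {
  rs <- list(paranoia = .26, hallucinations = .18, cogdis = .20,
             grandiosity = .04, anhedonia = .00, negsym = .12)
  expect_equal(correlation_gate(rs, .25), "paranoia")
  expect_equal(correlation_gate(list(a = .25), .25), character(0))
  expect_equal(correlation_gate(list(), .25), character(0))
  expect_error(correlation_gate(rs, 1.2), "threshold")
})
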