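## Descriptive surfaces of a twin study: per-scale moments and reliability,
## sex-by-zygosity ANOVA, phenotypic correlations on one random twin per
## pair, and the zygosity-specific twin correlations that motivate (or gate)
## variance-component modelling.

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a sum score:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`.
#' Rows with any missing item are dropped.
#'
#' @param items matrix or data frame of item responses (one row per person).
#' @return a single number.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  check_that(k >= 2, "alpha needs at least 2 items")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pairwise-complete Pearson correlation between two vectors with a 95%
#' (by default) Fisher-z interval, as used for phenotypic exposure-outcome
#' correlations on one random member per pair.
#'
#' @param x,y numeric vectors of equal length.
#' @param level confidence level.
#' @return a `correlation_result`: list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  check_that(sum(ok) >= 4, "need at least 4 complete (x, y) pairs")
  if (stats::sd(x[ok]) == 0) stop("x has zero variance", call. = FALSE)
  if (stats::sd(y[ok]) == 0) stop("y has zero variance", call. = FALSE)
  r <- stats::cor(x[ok], y[ok])
  if (abs(r) < 1) {
    ct <- stats::cor.test(x[ok], y[ok], conf.level = level)
    ci <- as.numeric(ct$conf.int)
  } else {
    ci <- c(r, r)
  }
  correlation_result(r, ci[1], ci[2], sum(ok))
}

correlation_result <- function(r, ci_low, ci_high, n) {
  structure(list(r = r, ci_low = ci_low, ci_high = ci_high, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%.3f, %.3f), n = %d\n",
              x$r, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Descriptive summary of a scale
#'
#' Reproduces the standard per-scale descriptive row of a twin study: means
#' and SDs on the raw scale (overall, by sex, by zygosity), score range,
#' skewness and non-excess kurtosis of the transformed scores, Cronbach's
#' alpha from item-level data when supplied, and a two-way fixed-effects
#' ANOVA (sex, zygosity, interaction; type-II sums of squares) on one random
#' member per pair, with p-values and the total R-squared of the sex +
#' zygosity + interaction model.
#'
#' @param pairs pair table carrying the trait's raw scores.
#' @param trait trait name.
#' @param items optional per-person item response table for alpha.
#' @param transformed optional pair table of transformed scores for the same
#'   trait (defaults to [sqrt_transform()] of the raw scores).
#' @param seed seed for the random-member selection.
#' @return a `descriptives_row` list.
#' @export
describe_scale <- function(pairs, trait, items = NULL, transformed = NULL,
                           seed = NULL) {
  df <- as.data.frame(pairs)
  raw <- trait_matrix(df, trait)
  vals <- as.vector(raw)
  check_that(sum(!is.na(vals)) >= 2, "need at least 2 non-missing values")
  tr_vals <- if (is.null(transformed)) {
    sqrt_transform(vals)
  } else {
    as.vector(trait_matrix(as.data.frame(transformed), trait))
  }

  sex_long <- c(df$sex_1, df$sex_2)
  zyg_long <- rep(df$zygosity, 2)
  cell_stats <- function(v) c(mean = mean(v, na.rm = TRUE),
                              sd = stats::sd(v, na.rm = TRUE))
  group_cell <- function(mask) {
    if (sum(!is.na(vals[mask])) < 2) {
      warning("empty or near-empty descriptive cell; reporting NA")
      return(c(mean = NA_real_, sd = NA_real_))
    }
    cell_stats(vals[mask])
  }

  person <- select_random_member(df, seed = seed)
  person$sex <- factor(person$sex, levels = c("male", "female"))
  person$zygosity <- factor(person$zygosity, levels = c("MZ", "DZ"))
  person$y <- person[[trait]]
  anova_block <- anova_sex_zyg(person)

  structure(list(
    trait = trait,
    mean_sd_total = cell_stats(vals),
    mean_sd_male = group_cell(sex_long == "male"),
    mean_sd_female = group_cell(sex_long == "female"),
    mean_sd_mz = group_cell(zyg_long == "MZ"),
    mean_sd_dz = group_cell(zyg_long == "DZ"),
    score_range = range(vals, na.rm = TRUE),
    skew = skewness(tr_vals),
    kurtosis = kurtosis(tr_vals),
    alpha = if (is.null(items)) NA_real_ else cronbach_alpha(items),
    p_sex = anova_block$p_sex,
    p_zyg = anova_block$p_zyg,
    p_sex_zyg = anova_block$p_sex_zyg,
    r_squared = anova_block$r_squared,
    n_anova = anova_block$n
  ), class = "descriptives_row")
}

## Two-way type-II ANOVA of the trait on sex and zygosity, one person per
## family; delegates the sums-of-squares bookkeeping to car::Anova.
anova_sex_zyg <- function(person) {
  ok <- !is.na(person$y)
  d <- person[ok, , drop = FALSE]
  fit <- stats::lm(y ~ sex * zygosity, data = d)
  tab <- car::Anova(fit, type = 2)
  p <- tab[["Pr(>F)"]]
  rn <- rownames(tab)
  list(p_sex = p[rn == "sex"],
       p_zyg = p[rn == "zygosity"],
       p_sex_zyg = p[rn == "sex:zygosity"],
       r_squared = summary(fit)$r.squared,
       n = nrow(d))
}

#' Twin correlations by zygosity
#'
#' Intraclass correlations (ICC) per zygosity via the double-entry Pearson
#' correlation (each pair contributes both twin orderings), and — when a
#' second trait is supplied — cross-twin cross-trait (CTCT) correlations per
#' zygosity, double-entered over both (X1, Y2) and (X2, Y1) orderings.
#' Confidence intervals use the Fisher z transform with effective n equal to
#' the number of contributing pairs (the double entry itself carries no new
#' information).
#'
#' @param pairs pair table of (preprocessed) trait values.
#' @param trait_x trait name.
#' @param trait_y optional second trait for CTCT correlations.
#' @param min_pairs minimum complete pairs per zygosity (default 10).
#' @return a `twin_correlations` list with elements `icc_mz`, `icc_dz` and,
#'   bivariately, `ctct_mz`, `ctct_dz` (each a `correlation_result`).
#' @export
twin_correlations <- function(pairs, trait_x, trait_y = NULL, min_pairs = 10) {
  out <- list()
  for (zyg in c("MZ", "DZ")) {
    x <- trait_matrix(pairs, trait_x, zyg)
    ok <- stats::complete.cases(x)
    if (sum(ok) < min_pairs) {
      stop(sprintf("only %d complete %s pairs for '%s' (need %d)",
                   sum(ok), zyg, trait_x, min_pairs), call. = FALSE)
    }
    out[[paste0("icc_", tolower(zyg))]] <-
      double_entry_cor(x[ok, 1], x[ok, 2], n_eff = sum(ok))
    if (!is.null(trait_y)) {
      y <- trait_matrix(pairs, trait_y, zyg)
      okb <- stats::complete.cases(cbind(x, y))
      if (sum(okb) < min_pairs) {
        stop(sprintf("only %d complete %s pairs for '%s'/'%s' (need %d)",
                     sum(okb), zyg, trait_x, trait_y, min_pairs),
             call. = FALSE)
      }
      out[[paste0("ctct_", tolower(zyg))]] <- double_entry_cor(
        c(x[okb, 1], x[okb, 2]), c(y[okb, 2], y[okb, 1]),
        n_eff = sum(okb), entered = TRUE)
    }
  }
  structure(out, class = "twin_correlations")
}

## Double-entry Pearson correlation: r over both orderings; CI on n_eff pairs.
double_entry_cor <- function(a, b, n_eff, entered = FALSE) {
  if (!entered) {
    x <- c(a, b); y <- c(b, a)
  } else {
    x <- a; y <- b
  }
  r <- stats::cor(x, y)
  ci <- fisher_z_ci(r, n_eff)
  correlation_result(r, ci[["lower"]], ci[["upper"]], n_eff)
}

#' Gate trait pairs for twin-model fitting
#'
#' Returns the names of trait pairs whose phenotypic correlation is strictly
#' greater than `threshold` — the rule used to decide which exposure-outcome
#' associations carry enough covariation to warrant bivariate twin modelling.
#'
#' @param correlations named list of `correlation_result`s (or bare numbers).
#' @param threshold gate threshold in `(0, 1)`; default 0.25.
#' @return character vector of names passing the gate (possibly empty).
#' @export
correlation_gate <- function(correlations, threshold = 0.25) {
  check_that(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  if (length(correlations) == 0) return(character(0))
  rs <- vapply(correlations, function(x) {
    if (inherits(x, "correlation_result")) x$r else as.numeric(x)
  }, numeric(1))
  names(rs)[rs > threshold]
}
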