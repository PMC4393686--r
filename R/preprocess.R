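## Preprocessing: scale scoring, square-root normalization, and removal of
## sex/age effects, mirroring standard behavioural-genetic practice.
##
## Order of operations is score -> sqrt -> residualize: the square root is
## only defined for the non-negative raw totals, so normalization must come
## before residualization (whose output is centred and partly negative).

#' Define a questionnaire scale
#'
#' @param name scale name.
#' @param items character vector of item column names (at least one).
#' @param range length-2 numeric: admissible per-item response range
#'   (e.g. `c(0, 2)` for "Not at all" / "Once" / "More than once").
#' @return an object of class `"scale_definition"`.
#' @export
scale_definition <- function(name, items, range) {
  check_that(length(items) >= 1, "a scale needs at least one item")
  check_that(length(range) == 2 && range[1] < range[2],
             "range must be c(min, max) with min < max")
  structure(list(name = name, items = items, range = range),
            class = "scale_definition")
}

#' Score a scale by summing items
#'
#' Total composite score per person: the sum of item responses. Persons
#' failing the missing-item policy receive a missing total.
#'
#' @param items data frame or matrix of item responses (one row per person).
#' @param scale a [scale_definition()].
#' @param missing_policy `"complete"` (total is missing if ANY item is
#'   missing; default, conservative) or `"prorate"` (mean of observed items
#'   rescaled to the full item count; total missing only if all items are).
#' @return numeric vector of totals.
#' @export
score_scale <- function(items, scale, missing_policy = c("complete", "prorate")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(scale, "scale_definition"))
  items <- as.data.frame(items)
  absent <- setdiff(scale$items, names(items))
  check_that(length(absent) == 0,
             paste("items missing from response table:",
                   paste(absent, collapse = ", ")))
  m <- as.matrix(items[scale$items])
  bad <- which(!is.na(m) & (m < scale$range[1] | m > scale$range[2]),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("out-of-range response in item '%s' (row %d): %g",
                 scale$items[bad[1, 2]], bad[1, 1], m[bad[1, , drop = FALSE]]),
         call. = FALSE)
  }
  if (missing_policy == "complete") {
    total <- rowSums(m)              # any NA propagates
  } else {
    k <- length(scale$items)
    total <- rowMeans(m, na.rm = TRUE) * k
    total[rowSums(!is.na(m)) == 0] <- NA_real_
  }
  total
}

#' Square-root transform of non-negative scores
#'
#' Element-wise square root, used to reduce the skewness and kurtosis of
#' bounded symptom/victimization totals before normal-theory twin modelling.
#' Missing values propagate.
#'
#' @param scores non-negative numeric vector.
#' @return transformed vector.
#' @export
sqrt_transform <- function(scores) {
  if (any(scores < 0, na.rm = TRUE)) {
    stop("sqrt_transform requires non-negative scores", call. = FALSE)
  }
  sqrt(scores)
}

#' Regress out sex and age and standardize the residuals
#'
#' Ordinary-least-squares residuals of `scores` on an intercept, a sex
#' contrast (male = 1, female = 0) and age, rescaled to mean 0 and variance 1
#' over non-missing entries. A predictor that is constant on the complete
#' rows is dropped with a warning. Residuals are exactly uncorrelated with
#' the retained predictors.
#'
#' @param scores numeric vector (missing allowed; missing stays missing).
#' @param sex character (`"male"`/`"female"`) or 0/1 numeric vector.
#' @param age numeric vector.
#' @return standardized residual vector, same length as `scores`.
#' @export
residualize <- function(scores, sex, age) {
  if (all(is.na(scores))) stop("all scores are missing", call. = FALSE)
  sex_num <- if (is.numeric(sex)) sex else as.numeric(sex == "male")
  X <- cbind(intercept = 1, sex = sex_num, age = age)
  ok <- !is.na(scores) & stats::complete.cases(X)
  check_that(sum(ok) >= 3, "need at least 3 complete rows to residualize")
  keep <- c(TRUE, apply(X[ok, -1, drop = FALSE], 2, function(col) {
    stats::var(col) > 0
  }))
  if (!all(keep)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(colnames(X)[-1][!keep[-1]], collapse = ", ")))
  }
  Xk <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xk[ok, , drop = FALSE], scores[ok])
  res <- rep(NA_real_, length(scores))
  res[ok] <- fit$residuals
  res[ok] <- (res[ok] - mean(res[ok])) / stats::sd(res[ok])
  res
}

#' Select one random member of each twin pair
#'
#' Converts a pair table to a person table with exactly one twin per family,
#' chosen uniformly at random (reproducibly under `seed`). Used for analyses
#' that require independent observations (ANOVA, phenotypic correlations).
#'
#' @param pairs a `twin_cohort` or compatible pair table.
#' @param seed integer seed.
#' @return data frame with one row per family: `family_id`, `zygosity`,
#'   `sex`, `age`, `member` (1 or 2) and one column per trait.
#' @export
select_random_member <- function(pairs, seed = NULL) {
  df <- as.data.frame(pairs)
  check_that(nrow(df) > 0, "pair table is empty")
  traits <- cohort_traits(df)
  with_seed(seed, {
    member <- sample(1:2, nrow(df), replace = TRUE)
    out <- data.frame(family_id = df$family_id, zygosity = as.character(df$zygosity),
                      sex = ifelse(member == 1, as.character(df$sex_1),
                                   as.character(df$sex_2)),
                      age = df$age, member = member,
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      out[[tr]] <- ifelse(member == 1, df[[paste0(tr, "_1")]],
                          df[[paste0(tr, "_2")]])
    }
    out
  })
}

#' Preprocess a trait within a cohort
#'
#' Applies the study preprocessing to one trait of a pair table:
#' square-root transform (optional, for non-negative raw scores) followed by
#' regression of sex and age out of the person-level values (both twins
#' stacked in a single regression) and standardization of the residuals.
#' The pair structure and family count are unchanged.
#'
#' @param pairs a `twin_cohort` or compatible pair table.
#' @param trait trait name.
#' @param transform apply [sqrt_transform()] first (default `TRUE` for raw
#'   scale totals; use `FALSE` for already-continuous values).
#' @return the cohort with the trait's columns replaced by processed values.
#' @export
preprocess_trait <- function(pairs, trait, transform = TRUE) {
  df <- as.data.frame(pairs)
  cols <- paste0(trait, "_", 1:2)
  check_that(all(cols %in% names(df)),
             sprintf("trait '%s' not present in cohort", trait))
  long <- data.frame(
    score = c(df[[cols[1]]], df[[cols[2]]]),
    sex = c(df$sex_1, df$sex_2),
    age = rep(df$age, 2))
  if (transform) long$score <- sqrt_transform(long$score)
  res <- residualize(long$score, long$sex, long$age)
  n <- nrow(df)
  df[[cols[1]]] <- res[seq_len(n)]
  df[[cols[2]]] <- res[n + seq_len(n)]
  finish_cohort(df, attr(pairs, "traits") %||% cohort_traits(df),
                attr(pairs, "gen_spec"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
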