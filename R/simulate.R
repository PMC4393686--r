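## Synthetic twin cohorts with known ACE structure.
##
## Latent trait construction (unit marginal variance before sex/age shifts):
##   y_twin = a*A_twin + c*C_family + e*E_twin
## with C shared within a pair, E independent, and the additive component
## correlated 1.0 (MZ) or exactly 0.5 (DZ) across co-twins via
##   A_twin = A_family                      (MZ)
##   A_twin = sqrt(.5)*A_family + sqrt(.5)*A_individual   (DZ)

#' Specification for a univariate ACE twin simulation
#'
#' Describes the generative model for one quantitative trait measured on
#' monozygotic (MZ) and dizygotic (DZ) twin pairs: standardized variance
#' components `a2` (additive genetic), `c2` (common environment) and `e2`
#' (unique environment), which must be non-negative and sum to 1.
#'
#' Small linear sex and age effects (defaults 0.1 SD per sex contrast and
#' 0.05 SD per year of age) are added so that the residualization stage of
#' preprocessing has real signal to remove; both can be set to 0.
#'
#' @param a2,c2,e2 standardized variance proportions in `[0,1]`, summing to 1.
#' @param mean trait mean on the latent scale.
#' @param n_mz,n_dz numbers of MZ and DZ pairs (each at least 1).
#' @param missing_rate element-wise MCAR missingness probability in `[0,1)`.
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @param trait trait name used for the cohort's value columns.
#' @param beta_sex additive shift for males (sex coded male = 1).
#' @param beta_age additive shift per year of age, centred on the midpoint of
#'   `age_range`.
#' @param age_range range of pair ages (years), sampled uniformly per pair.
#' @return an object of class `"univariate_gen_spec"`.
#' @export
univariate_gen_spec <- function(a2, c2, e2, mean = 0, n_mz, n_dz,
                                missing_rate = 0, seed = NULL,
                                trait = "trait",
                                beta_sex = 0.1, beta_age = 0.05,
                                age_range = c(15.5, 17.5)) {
  check_that(is.numeric(a2) && a2 >= 0, "a2 must be a non-negative number")
  check_that(is.numeric(c2) && c2 >= 0, "c2 must be a non-negative number")
  check_that(is.numeric(e2) && e2 >= 0, "e2 must be a non-negative number")
  check_that(abs(a2 + c2 + e2 - 1) <= 1e-12,
             "a2 + c2 + e2 must sum to 1 (within 1e-12)")
  check_that(n_mz >= 1 && n_dz >= 1, "n_mz and n_dz must each be at least 1")
  check_that(missing_rate >= 0 && missing_rate < 1,
             "missing_rate must lie in [0, 1)")
  structure(list(a2 = a2, c2 = c2, e2 = e2, mean = mean,
                 n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 missing_rate = missing_rate, seed = seed, trait = trait,
                 beta_sex = beta_sex, beta_age = beta_age,
                 age_range = age_range),
            class = "univariate_gen_spec")
}

#' Specification for a bivariate ACE twin simulation
#'
#' Generative model for two traits X and Y (e.g. a bullying-victimization-like
#' exposure and a paranoia-like outcome) measured on the same twin pairs,
#' following the correlated-factors parameterization: per-trait standardized
#' components plus factor correlations `r_a` (genetic), `r_c` (common
#' environment) and `r_e` (unique environment) between the traits.
#'
#' @param a2_x,c2_x,e2_x standardized components for trait X (sum to 1).
#' @param a2_y,c2_y,e2_y standardized components for trait Y (sum to 1).
#' @param r_a,r_c,r_e cross-trait factor correlations in `[-1, 1]`.
#' @param trait_x,trait_y trait names for the cohort's value columns.
#' @inheritParams univariate_gen_spec
#' @return an object of class `"bivariate_gen_spec"`.
#' @export
bivariate_gen_spec <- function(a2_x, c2_x, e2_x, a2_y, c2_y, e2_y,
                               r_a = 0, r_c = 0, r_e = 0,
                               n_mz, n_dz, missing_rate = 0, seed = NULL,
                               trait_x = "x", trait_y = "y",
                               beta_sex = 0.1, beta_age = 0.05,
                               age_range = c(15.5, 17.5)) {
  for (nm in c("a2_x", "c2_x", "e2_x", "a2_y", "c2_y", "e2_y")) {
    v <- get(nm)
    check_that(is.numeric(v) && v >= 0,
               sprintf("%s must be a non-negative number", nm))
  }
  check_that(abs(a2_x + c2_x + e2_x - 1) <= 1e-12,
             "trait X proportions must sum to 1 (within 1e-12)")
  check_that(abs(a2_y + c2_y + e2_y - 1) <= 1e-12,
             "trait Y proportions must sum to 1 (within 1e-12)")
  for (nm in c("r_a", "r_c", "r_e")) {
    v <- get(nm)
    check_that(abs(v) <= 1, sprintf("%s must lie in [-1, 1]", nm))
  }
  spec <- structure(list(a2_x = a2_x, c2_x = c2_x, e2_x = e2_x,
                         a2_y = a2_y, c2_y = c2_y, e2_y = e2_y,
                         r_a = r_a, r_c = r_c, r_e = r_e,
                         n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                         missing_rate = missing_rate, seed = seed,
                         trait_x = trait_x, trait_y = trait_y,
                         beta_sex = beta_sex, beta_age = beta_age,
                         age_range = age_range),
                    class = "bivariate_gen_spec")
  pars <- gen_spec_params(spec)
  for (zyg in c("MZ", "DZ")) {
    sig <- expected_cov_bivariate(pars, zyg)
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop(sprintf(
        "implied %s covariance is not positive semidefinite (eigenvalue %.3g)",
        zyg, min(ev)), call. = FALSE)
    }
  }
  spec
}

## Path-coefficient view of a bivariate generating spec (unit variances).
gen_spec_params <- function(spec) {
  bivariate_ace_params(
    a_x = sqrt(spec$a2_x), c_x = sqrt(spec$c2_x), e_x = sqrt(spec$e2_x),
    a_y = sqrt(spec$a2_y), c_y = sqrt(spec$c2_y), e_y = sqrt(spec$e2_y),
    r_a = spec$r_a, r_c = spec$r_c, r_e = spec$r_e)
}

## Shared demographic scaffolding for a cohort: pair ids, zygosity, sexes
## (MZ pairs always same-sex; DZ co-twin sexes independent), shared pair age.
simulate_demographics <- function(n_mz, n_dz, age_range) {
  n <- n_mz + n_dz
  zygosity <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  sex_1 <- sample(c("male", "female"), n, replace = TRUE)
  sex_2 <- ifelse(zygosity == "MZ", sex_1,
                  sample(c("male", "female"), n, replace = TRUE))
  age <- stats::runif(n, age_range[1], age_range[2])
  data.frame(family_id = sprintf("fam%05d", seq_len(n)),
             zygosity = zygosity, sex_1 = sex_1, sex_2 = sex_2, age = age,
             stringsAsFactors = FALSE)
}

## Per-twin additive-genetic factor scores with cross-twin correlation
## 1 (MZ) / 0.5 (DZ). `fam`, `ind1`, `ind2` are iid latent draws.
mix_additive <- function(fam, ind, mz) {
  ifelse(mz, fam, sqrt(0.5) * fam + sqrt(0.5) * ind)
}

apply_sex_age <- function(y, sex, age, age_range, beta_sex, beta_age) {
  y + beta_sex * (sex == "male") + beta_age * (age - mean(age_range))
}

## Element-wise MCAR mask over the trait columns; guarantees that no pair
## ends up with every trait value missing (one random entry is restored).
apply_missingness <- function(cohort, trait_cols, rate) {
  if (rate <= 0) return(cohort)
  vals <- as.matrix(cohort[trait_cols])
  mask <- matrix(stats::runif(length(vals)) < rate, nrow = nrow(vals))
  vals[mask] <- NA_real_
  all_gone <- rowSums(!is.na(vals)) == 0
  if (any(all_gone)) {
    keep <- sample.int(ncol(vals), sum(all_gone), replace = TRUE)
    orig <- as.matrix(cohort[trait_cols])
    vals[cbind(which(all_gone), keep)] <- orig[cbind(which(all_gone), keep)]
  }
  cohort[trait_cols] <- as.data.frame(vals)
  cohort
}

finish_cohort <- function(cohort, traits, spec) {
  structure(cohort, traits = traits, gen_spec = spec,
            class = c("twin_cohort", "data.frame"))
}

#' Simulate a univariate twin cohort
#'
#' Draws MZ and DZ twin pairs from the additive-genetic / common-environment /
#' unique-environment (ACE) generative model at the proportions in `spec`.
#' The latent trait has unit variance; small linear sex and age effects are
#' added on top (see [univariate_gen_spec()]); element-wise MCAR missingness
#' is applied last.
#'
#' @param spec a [univariate_gen_spec()].
#' @return a `twin_cohort` data frame with columns `family_id`, `zygosity`,
#'   `sex_1`, `sex_2`, `age` and `<trait>_1`, `<trait>_2`.
#' @examples
#' spec <- univariate_gen_spec(a2 = .35, c2 = .26, e2 = .39,
#'                             n_mz = 200, n_dz = 200, seed = 1)
#' cohort <- simulate_univariate(spec)
#' head(cohort)
#' @export
simulate_univariate <- function(spec) {
  stopifnot(inherits(spec, "univariate_gen_spec"))
  with_seed(spec$seed, {
    n <- spec$n_mz + spec$n_dz
    demo <- simulate_demographics(spec$n_mz, spec$n_dz, spec$age_range)
    mz <- demo$zygosity == "MZ"
    a <- sqrt(spec$a2); c_ <- sqrt(spec$c2); e <- sqrt(spec$e2)
    A_fam <- stats::rnorm(n)
    C_fam <- stats::rnorm(n)
    y <- lapply(1:2, function(k) {
      A <- mix_additive(A_fam, stats::rnorm(n), mz)
      spec$mean + a * A + c_ * C_fam + e * stats::rnorm(n)
    })
    sex <- list(demo$sex_1, demo$sex_2)
    for (k in 1:2) {
      demo[[paste0(spec$trait, "_", k)]] <- apply_sex_age(
        y[[k]], sex[[k]], demo$age, spec$age_range,
        spec$beta_sex, spec$beta_age)
    }
    cols <- paste0(spec$trait, "_", 1:2)
    demo <- apply_missingness(demo, cols, spec$missing_rate)
    finish_cohort(demo, spec$trait, spec)
  })
}

#' Simulate a bivariate twin cohort
#'
#' Draws twin pairs carrying two traits from the correlated-factors bivariate
#' ACE model: each trait follows its own ACE decomposition and the A, C and E
#' factors of the two traits correlate `r_a`, `r_c` and `r_e` respectively.
#' Sample moments converge to [expected_cov_bivariate()] applied to the
#' generating parameters.
#'
#' @param spec a [bivariate_gen_spec()].
#' @return a `twin_cohort` data frame with value columns `<trait_x>_1`,
#'   `<trait_x>_2`, `<trait_y>_1`, `<trait_y>_2`.
#' @export
simulate_bivariate <- function(spec) {
  stopifnot(inherits(spec, "bivariate_gen_spec"))
  with_seed(spec$seed, {
    n <- spec$n_mz + spec$n_dz
    demo <- simulate_demographics(spec$n_mz, spec$n_dz, spec$age_range)
    mz <- demo$zygosity == "MZ"
    a_x <- sqrt(spec$a2_x); c_x <- sqrt(spec$c2_x); e_x <- sqrt(spec$e2_x)
    a_y <- sqrt(spec$a2_y); c_y <- sqrt(spec$c2_y); e_y <- sqrt(spec$e2_y)
    A_fam <- rbinorm(n, spec$r_a)
    C_fam <- rbinorm(n, spec$r_c)
    sex <- list(demo$sex_1, demo$sex_2)
    for (k in 1:2) {
      ## each twin's individual additive part must carry the same cross-trait
      ## correlation r_a, so draw the (X, Y) individual pair jointly
      A_ind <- rbinorm(n, spec$r_a)
      A <- cbind(mix_additive(A_fam[, 1], A_ind[, 1], mz),
                 mix_additive(A_fam[, 2], A_ind[, 2], mz))
      E <- rbinorm(n, spec$r_e)
      x <- a_x * A[, 1] + c_x * C_fam[, 1] + e_x * E[, 1]
      y <- a_y * A[, 2] + c_y * C_fam[, 2] + e_y * E[, 2]
      demo[[paste0(spec$trait_x, "_", k)]] <- apply_sex_age(
        x, sex[[k]], demo$age, spec$age_range, spec$beta_sex, spec$beta_age)
      demo[[paste0(spec$trait_y, "_", k)]] <- apply_sex_age(
        y, sex[[k]], demo$age, spec$age_range, spec$beta_sex, spec$beta_age)
    }
    cols <- c(paste0(spec$trait_x, "_", 1:2), paste0(spec$trait_y, "_", 1:2))
    demo <- apply_missingness(demo, cols, spec$missing_rate)
    finish_cohort(demo, c(spec$trait_x, spec$trait_y), spec)
  })
}

#' Simulate parallel item responses
#'
#' Generates `k` parallel items (equal variance, common pairwise correlation
#' `rho`) for `n` persons — a fixture for internal-consistency (Cronbach's
#' alpha) computations. Under this model the population alpha equals the
#' Spearman-Brown value `k*rho / (1 + (k-1)*rho)`.
#'
#' @param k number of items (at least 2).
#' @param rho common inter-item correlation in `[0, 1)`; `rho = 1` is allowed
#'   as the degenerate identical-items case.
#' @param n number of persons.
#' @param seed integer seed.
#' @return an `n` by `k` numeric matrix with columns `item1..itemk`.
#' @export
simulate_items <- function(k, rho, n, seed = NULL) {
  check_that(k >= 2, "k must be at least 2")
  check_that(rho >= 0 && rho <= 1, "rho must lie in [0, 1]")
  ## equicorrelation matrix is PSD iff rho >= -1/(k-1); non-negative rho
  ## always qualifies, so only the upper degenerate case needs care
  with_seed(seed, {
    common <- stats::rnorm(n)
    if (rho == 1) {
      out <- matrix(rep(common, k), nrow = n)
    } else {
      uniq <- matrix(stats::rnorm(n * k), nrow = n)
      out <- sqrt(rho) * common + sqrt(1 - rho) * uniq
    }
    colnames(out) <- paste0("item", seq_len(k))
    out
  })
}

#' Map latent values onto a bounded, positively skewed raw scale
#'
#' Monotone transform of latent values onto an integer-like questionnaire
#' range, producing the positive skew typical of symptom and victimization
#' scales, so that the square-root-transform path of preprocessing is
#' exercised on realistic input. The latent values are mapped through their
#' empirical ranks, raised to `skew_power` (values above 1 pile mass near the
#' minimum), scaled to `[target_min, target_max]` and optionally rounded.
#'
#' @param latent numeric vector (NAs pass through).
#' @param target_min,target_max bounds of the raw scale.
#' @param skew_power exponent applied to the uniformized values; `> 1` gives
#'   positive skew, `1` leaves the distribution uniform over the range.
#' @param rounding round to integers (default `TRUE`).
#' @return numeric vector within `[target_min, target_max]`.
#' @export
apply_raw_scale <- function(latent, target_min = 0, target_max = 32,
                            skew_power = 3, rounding = TRUE) {
  check_that(target_min < target_max, "target_min must be below target_max")
  check_that(skew_power > 0, "skew_power must be positive")
  ok <- !is.na(latent)
  out <- rep(NA_real_, length(latent))
  n <- sum(ok)
  if (n == 0) return(out)
  if (n == 1 || stats::sd(latent[ok]) == 0) {
    u <- rep(0.5, n)
  } else {
    u <- (rank(latent[ok], ties.method = "average") - 0.5) / n
  }
  raw <- target_min + (target_max - target_min) * u^skew_power
  if (rounding) raw <- round(raw)
  out[ok] <- pmin(pmax(raw, target_min), target_max)
  out
}
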