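## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Preprocessed univariate cohort at the bullying-like ACE solution.
bullying_cohort <- function() {
  cached("bullying", function() {
    spec <- univariate_gen_spec(a2 = .35, c2 = .26, e2 = .39,
                                n_mz = 1418, n_dz = 1258,
                                seed = 401, trait = "bully")
    preprocess_trait(simulate_univariate(spec), "bully", transform = FALSE)
  })
}

## Preprocessed bivariate cohort at the published best-fit solution.
study_cohort <- function(missing_rate = 0, seed = 402) {
  key <- sprintf("study_%g_%d", missing_rate, seed)
  cached(key, function() {
    co <- simulate_bivariate(default_study_spec(seed = seed,
                                                missing_rate = missing_rate))
    for (tr in c("bullying", "paranoia")) {
      co <- preprocess_trait(co, tr, transform = FALSE)
    }
    co
  })
}

## Data matrix whose ML (divide-by-n) sample moments exactly match a target
## mean vector and covariance: empirical whitening followed by colouring.
moment_matched <- function(n, mu, sigma, seed) {
  set.seed(seed)
  p <- length(mu)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- sweep(Z, 2, colMeans(Z))
  S <- crossprod(Z) / n
  Z <- Z %*% solve(chol(S))
  sweep(Z %*% chol(sigma), 2, mu, `+`)
}

## Row-wise FIML oracle: sum of -2 log multivariate-normal densities over
## each row's observed subvector (independent of the package's
## sufficient-statistic evaluation path).
rowwise_neg2ll <- function(Y, mu, sigma) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    S <- sigma[obs, obs, drop = FALSE]
    d <- Y[i, obs] - mu[obs]
    total <- total + length(obs) * log(2 * pi) +
      determinant(S, logarithm = TRUE)$modulus[1] +
      drop(t(d) %*% solve(S) %*% d)
  }
  total
}
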