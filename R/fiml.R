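## Full-information maximum likelihood for multivariate-normal pair data
## with item-level missingness.
##
## The -2 log-likelihood decomposes over missingness patterns: for each
## pattern (subset of observed variables) with n rows, mean xbar and scatter
## matrix S* = sum (x - xbar)(x - xbar)',
##   -2LL = n k log(2*pi) + n log|Sigma_oo| +
##          tr(Sigma_oo^-1 [S* + n (xbar - mu_o)(xbar - mu_o)'])
## so the per-pattern sufficient statistics are computed once per dataset and
## every likelihood evaluation is O(#patterns), independent of sample size.

## Precompute per-pattern sufficient statistics for an n x p data matrix.
fiml_prepare <- function(Y) {
  Y <- as.matrix(Y)
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0)) {
    stop("rows with no observed values are not allowed in the likelihood",
         call. = FALSE)
  }
  keys <- apply(obs, 1, function(o) paste(which(o), collapse = ","))
  patterns <- lapply(split(seq_len(nrow(Y)), keys), function(rows) {
    cols <- which(obs[rows[1], ])
    X <- Y[rows, cols, drop = FALSE]
    n <- nrow(X)
    xbar <- colMeans(X)
    centred <- sweep(X, 2, xbar)
    list(cols = cols, n = n, xbar = xbar, scatter = crossprod(centred))
  })
  structure(list(patterns = patterns, n_rows = nrow(Y), n_obs = sum(obs),
                 p = ncol(Y)),
            class = "fiml_prep")
}

fiml_neg2ll_prep <- function(prep, mu, sigma) {
  total <- 0
  for (pat in prep$patterns) {
    k <- length(pat$cols)
    S <- sigma[pat$cols, pat$cols, drop = FALSE]
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L)) {
      stop(sprintf(
        "singular implied covariance for observed pattern {%s}",
        paste(pat$cols, collapse = ",")), call. = FALSE)
    }
    logdet <- 2 * sum(log(diag(L)))
    Sinv <- chol2inv(L)
    d <- pat$xbar - mu[pat$cols]
    quad <- sum(Sinv * (pat$scatter + pat$n * tcrossprod(d)))
    total <- total + pat$n * (k * log(2 * pi) + logdet) + quad
  }
  total
}

## As above but returns +Inf instead of stopping on an indefinite Sigma,
## for use inside optimizers.
fiml_neg2ll_safe <- function(prep, mu, sigma) {
  out <- tryCatch(fiml_neg2ll_prep(prep, mu, sigma), error = function(e) Inf)
  if (!is.finite(out)) Inf else out
}

#' FIML -2 log-likelihood of pair data under implied moments
#'
#' Evaluates the full-information maximum-likelihood \eqn{-2\log L} of a data
#' matrix (rows = twin pairs, columns = per-twin values, `NA` = missing)
#' under a multivariate-normal model with mean `mu` and covariance `sigma`:
#' each row contributes the normal log-density of its observed subvector
#' under the matching rows/columns of `mu` and `sigma`.
#'
#' @param data numeric matrix; every row must have at least one observed
#'   value.
#' @param mu mean vector of length `ncol(data)`.
#' @param sigma covariance matrix, `ncol(data)` square.
#' @return the scalar \eqn{-2\log L}.
#' @export
fiml_neg2ll <- function(data, mu, sigma) {
  prep <- fiml_prepare(data)
  check_that(length(mu) == prep$p && all(dim(sigma) == prep$p),
             "mu and sigma must match the number of data columns")
  fiml_neg2ll_prep(prep, mu, sigma)
}
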