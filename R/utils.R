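#' @keywords internal
"_PACKAGE"

## Moment-based shape statistics. Kurtosis uses the non-excess convention
## (Gaussian = 3), the convention used for twin-scale descriptives here.

#' Moment skewness and kurtosis
#'
#' Population-moment estimators: skewness \eqn{m_3/m_2^{3/2}} and non-excess
#' kurtosis \eqn{m_4/m_2^2} (so a normal distribution has kurtosis 3).
#' Missing values are dropped.
#'
#' @param x numeric vector.
#' @return a single number.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

#' @rdname skewness
#' @export
kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^4) / m2^2
}

## Fisher-z confidence interval for a correlation, on an effective n.
fisher_z_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - q * se), upper = tanh(z + q * se))
}

## Draw n rows from a zero-mean bivariate normal with correlation rho.
rbinorm <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

## Stop with a field-naming message unless cond holds.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Run an expression under a temporary RNG seed, restoring the caller's
## RNG state afterwards so simulation helpers do not disturb outer streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
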