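#' Box-Cox power transformation
#'
#' `boxcox_transform()` applies the power transform
#' `(y^lambda - 1) / lambda` (natural log when `lambda = 0`) after an optional
#' additive shift; `boxcox_backtransform()` inverts it.
#'
#' @param y Numeric vector, positive after adding `shift`.
#' @param lambda Power parameter.
#' @param shift Additive offset applied before transforming (default 0).
#' @param z Transformed values to invert.
#' @return Numeric vector of transformed (or back-transformed) values.
#' @seealso [boxcox_lambda_mle()]
#' @export
boxcox_transform <- function(y, lambda, shift = 0) {
  y <- y + shift
  if (any(y <= 0, na.rm = TRUE)) {
    abort("Box-Cox transform needs positive values; supply a `shift`.")
  }
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
boxcox_backtransform <- function(z, lambda, shift = 0) {
  out <- if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
  out - shift
}

#' Maximum-likelihood estimate of the Box-Cox power parameter
#'
#' Profiles the normal log-likelihood of the transformed data over `lambda`,
#' including the Jacobian term `(lambda - 1) * sum(log y)`, and maximizes it
#' with bounded scalar optimization. Zeros in `y` are handled by an additive
#' shift of half the smallest positive observation (the default when
#' `shift = NULL`); negative values are an error.
#'
#' @param y Positive numeric vector (zeros allowed when shifted).
#' @param shift Additive offset applied before transforming; `NULL` selects
#'   0 for all-positive data and half the smallest positive value when zeros
#'   are present.
#' @param interval Search bounds for `lambda` (default \[-3, 3\]).
#' @return A list of class `boxcox_fit` with elements `lambda`, `loglik`
#'   (profile log-likelihood at the optimum), `shift` and `n`.
#' @examples
#' y <- exp(rnorm(500))
#' boxcox_lambda_mle(y)$lambda # near 0 for log-normal data
#' @export
boxcox_lambda_mle <- function(y, shift = NULL, interval = c(-3, 3)) {
  y <- y[!is.na(y)]
  if (!length(y)) abort("No non-missing values to transform.")
  if (any(y < 0)) {
    abort("Negative values cannot be Box-Cox transformed; shift the data first.")
  }
  if (is.null(shift)) {
    shift <- if (any(y == 0)) {
      s <- min(y[y > 0]) / 2
      inform(sprintf(
        "boxcox_lambda_mle: %d zero value(s); applying shift = %.6g.",
        sum(y == 0), s
      ))
      s
    } else {
      0
    }
  }
  if (any(y + shift <= 0)) {
    abort("Values remain non-positive after `shift`; increase the shift.")
  }
  prof <- function(lambda) boxcox_profile_loglik(y, lambda, shift)
  opt <- optimize(prof, interval = interval, maximum = TRUE, tol = 1e-6)
  structure(
    list(
      lambda = opt$maximum,
      loglik = opt$objective,
      shift = shift,
      n = length(y)
    ),
    class = "boxcox_fit"
  )
}

# profile log-likelihood of the Box-Cox model at a given lambda:
# normal likelihood of transformed data (variance profiled out) plus the
# (lambda - 1) * sum(log y) Jacobian
boxcox_profile_loglik <- function(y, lambda, shift = 0) {
  z <- boxcox_transform(y, lambda, shift)
  n <- length(z)
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y + shift))
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf(
    "<boxcox_fit> lambda = %.4f, shift = %.4g, profile logLik = %.3f (n = %d)\n",
    x$lambda, x$shift, x$loglik, x$n
  ))
  invisible(x)
}
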