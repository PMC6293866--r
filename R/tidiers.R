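#' Tidy a conditional logistic fit
#'
#' @param x A `clogit_fit` object.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.clogit_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- unname(x$beta)
  se <- unname(x$se)
  out <- tibble::tibble(
    term = x$terms,
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * pnorm(-abs(est / se)),
    conf.low = est - z * se,
    conf.high = est + z * se
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a conditional logistic fit
#'
#' @param x A `clogit_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `logLik_null`, `n_sets`, `n_subjects`,
#'   `converged`, `iterations`.
#' @export
glance.clogit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    logLik_null = x$loglik_null,
    n_sets = x$n_sets,
    n_subjects = x$n_subjects,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' @rdname tidy.clogit_fit
#' @export
tidy.ulogit_fit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  tidy.clogit_fit(x, exponentiate = exponentiate, conf.level = conf.level, ...)
}

#' @rdname glance.clogit_fit
#' @export
glance.ulogit_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, converged = x$converged)
}

#' @rdname tidy.clogit_fit
#' @export
tidy.boxcox_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, loglik = x$loglik, shift = x$shift, n = x$n)
}

#' Tidy an adjusted measure
#'
#' @param x An `adjusted_measure` object.
#' @param ... Unused.
#' @return A one-row tibble with the adjustment coefficients, the
#'   unadjusted and adjusted SDs, and the control count.
#' @export
tidy.adjusted_measure <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    intercept = x$coefficients[["intercept"]],
    age = x$coefficients[["age"]],
    bmi = x$coefficients[["bmi"]],
    sd_unadjusted = x$sd_unadjusted,
    sd_adjusted = x$sd_adjusted,
    n_controls = x$n_controls
  )
}
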