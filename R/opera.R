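#' Odds ratio per adjusted standard deviation (OPERA) from a fitted model
#'
#' Exponentiates the coefficient of a unit-adjusted-SD standardized measure
#' to give the OPERA, with Wald 95% limits `exp(beta +/- 1.959964 * SE)` and
#' the corresponding inter-quartile risk ratio `OPERA^2.5`.
#'
#' @param fit A converged [fit_clogit()] (or [fit_unconditional_logit()])
#'   object.
#' @param terms Terms to report (default: all fitted terms).
#' @return A tibble of class `opera_result` with one row per term:
#'   `term`, `log_opera`, `se`, `opera`, `conf.low`, `conf.high`, `iqrr`,
#'   `loglik`.
#' @examples
#' cohort <- generate_matched_sets(sim_params(n_sets_screen = 0, seed = 1),
#'                                 keep_latent = TRUE)
#' opera_from_fit(fit_clogit(cohort, ".z_cumulus_pct"))
#' @export
opera_from_fit <- function(fit, terms = fit$terms) {
  if (!isTRUE(fit$converged)) {
    abort("Refusing to report OPERA from a non-converged fit; inspect the model (possible separation).")
  }
  missing_terms <- setdiff(terms, names(fit$beta))
  if (length(missing_terms)) {
    abort(paste0("Term(s) not in fit: ", paste(missing_terms, collapse = ", ")))
  }
  b <- fit$beta[terms]
  se <- fit$se[terms]
  out <- tibble::tibble(
    term = terms,
    log_opera = unname(b),
    se = unname(se),
    opera = exp(unname(b)),
    conf.low = exp(unname(b) - Z975 * unname(se)),
    conf.high = exp(unname(b) + Z975 * unname(se)),
    iqrr = iqrr(exp(unname(b))),
    loglik = fit$loglik
  )
  class(out) <- c("opera_result", class(out))
  out
}

#' Rescale jointly-fitted log odds ratios to bivariable OPERAs
#'
#' When two standardized measures are fitted together, the coefficient of
#' each is expressed per SD of that measure after adjusting for the other by
#' multiplying the log(OR) by `sqrt(1 - r^2)` (with `r` the correlation
#' between the two measures) before exponentiating. Confidence limits are
#' scaled identically.
#'
#' @param log_or Numeric vector of jointly-fitted log odds ratios.
#' @param r Correlation between the two standardized measures, `|r| < 1`
#'   (for three measures fitted together, supply each term's multiple
#'   correlation with the others).
#' @param se Optional standard errors for Wald limits.
#' @return A tibble: `log_opera` (scaled), `opera`, and when `se` is given
#'   `conf.low`/`conf.high`.
#' @examples
#' bivariable_opera(1, r = 0.82)$opera # exp(sqrt(1 - 0.82^2)) = 1.77
#' @export
bivariable_opera <- function(log_or, r, se = NULL) {
  if (any(abs(r) >= 1)) {
    abort("|r| = 1: the measures are indistinguishable and cannot be scaled.")
  }
  mult <- sqrt(1 - r^2)
  out <- tibble::tibble(
    log_opera = log_or * mult,
    opera = exp(log_or * mult)
  )
  if (!is.null(se)) {
    out$conf.low <- exp((log_or - Z975 * se) * mult)
    out$conf.high <- exp((log_or + Z975 * se) * mult)
  }
  out
}

#' Inter-quartile risk ratio implied by an OPERA
#'
#' The risk ratio between the top and bottom quartiles of a standardized
#' normal risk factor is approximately `OPERA^2.5`.
#'
#' @param opera Positive odds ratio(s) per adjusted SD.
#' @return `opera^2.5`, vectorized.
#' @examples
#' iqrr(2.33) # about 8-fold
#' @export
iqrr <- function(opera) {
  if (any(opera <= 0)) abort("`opera` must be positive.")
  opera^2.5
}

#' BIC difference, posterior odds and verbal strength of evidence
#'
#' For models with the same number of parameters the BIC difference is twice
#' the log-likelihood difference, `delta_bic = -2 * (ll_a - ll_b)` (negative
#' when model A fits better); with unequal parameter counts the
#' `(k_a - k_b) * log(n)` complexity term is added. The posterior odds in
#' favour of model A are read as `exp(-delta_bic)` (so -6 is roughly 400:1
#' and -14 roughly a million to one); `convention = "halved"` gives the
#' textbook `exp(-delta_bic / 2)` instead. Strength of evidence against the
#' poorer-fitting model is banded on `|delta_bic|` at 2 / 6 / 10:
#' `none`, `positive`, `strong`, `very strong`.
#'
#' @param ll_a,ll_b Maximized log-likelihoods of models A and B.
#' @param k_a,k_b Parameter counts (default equal).
#' @param n Number of observations, required when `k_a != k_b`.
#' @param convention `"paper"` (`exp(-delta_bic)`, default) or `"halved"`.
#' @return A one-row tibble of class `model_comparison`: `delta_ll`,
#'   `delta_bic`, `posterior_odds`, `equal_params`, `strength`.
#' @examples
#' delta_bic(ll_a = -100, ll_b = -103) # delta_bic = -6, odds ~ 400
#' @export
delta_bic <- function(ll_a, ll_b, k_a = 1L, k_b = k_a, n = NULL,
                      convention = c("paper", "halved")) {
  convention <- match.arg(convention)
  equal <- k_a == k_b
  db <- -2 * (ll_a - ll_b)
  if (!equal) {
    if (is.null(n) || n <= 0) {
      abort("`n` (a positive observation count) is required when parameter counts differ.")
    }
    db <- db + (k_a - k_b) * log(n)
  }
  odds <- if (convention == "paper") exp(-db) else exp(-db / 2)
  a <- abs(db)
  strength <- if (a < 2) "none" else if (a < 6) "positive" else if (a < 10) "strong" else "very strong"
  out <- tibble::tibble(
    delta_ll = ll_a - ll_b,
    delta_bic = db,
    posterior_odds = odds,
    equal_params = equal,
    strength = strength
  )
  class(out) <- c("model_comparison", class(out))
  out
}

#' Covariate-adjusted AUC of a standardized measure
#'
#' Area under the ROC curve of the (already adjusted and standardized)
#' measure pooled over subjects, by the Mann-Whitney estimator, with a
#' DeLong 95% confidence interval (via pROC).
#'
#' @param values Numeric standardized measure.
#' @param case_flag Logical or 0/1 case indicator; both classes must be
#'   present.
#' @return A one-row tibble: `auc`, `conf.low`, `conf.high`, `n_cases`,
#'   `n_controls`.
#' @export
auc_adjusted <- function(values, case_flag) {
  case_flag <- as.integer(as.logical(case_flag))
  if (length(unique(case_flag)) < 2L) {
    abort("Both cases and controls are required to compute an AUC.")
  }
  roc <- pROC::roc(
    response = case_flag, predictor = as.numeric(values),
    levels = c(0, 1), direction = "<", quiet = TRUE
  )
  ci <- as.numeric(pROC::ci.auc(roc, conf.level = 0.95, method = "delong"))
  tibble::tibble(
    auc = as.numeric(pROC::auc(roc)),
    conf.low = ci[1], conf.high = ci[3],
    n_cases = sum(case_flag == 1L), n_controls = sum(case_flag == 0L)
  )
}

#' Quartile odds ratios of an adjusted measure
#'
#' Residualizes the standardized measure on the requested covariates among
#' controls, cuts the whole cohort at the control 25/50/75 percentiles of
#' the adjusted values, and fits the three upper-quartile indicators by
#' conditional logistic regression, giving odds ratios for Q2-Q4 versus Q1.
#'
#' @param data A standardized cohort (one outcome mode).
#' @param measure Name of the standardized measure column.
#' @param covariates Covariates defining the quartile adjustment (default
#'   age, BMI and live births).
#' @param set,case Matched-set id and case-flag column names.
#' @return A tibble with rows Q1-Q4: `quartile`, `n_cases`, `or`,
#'   `conf.low`, `conf.high` (Q1 is the reference with OR 1), plus the fit
#'   log-likelihood as attribute `"fit"`.
#' @export
quartile_ors <- function(data, measure,
                         covariates = c("age", "bmi", "livebirths"),
                         set = "set_id", case = "case") {
  for (col in c(measure, covariates, set, case)) {
    if (!col %in% names(data)) abort(paste0("Column not found: ", col))
  }
  ctl <- data[[case]] == 0
  X <- cbind(1, as.matrix(data[covariates]))
  coefs <- qr.coef(qr(X[ctl, , drop = FALSE]), data[[measure]][ctl])
  coefs[is.na(coefs)] <- 0 # collinear adjustment columns carry no signal
  adj <- data[[measure]] - drop(X %*% coefs)
  cuts <- quantile(adj[ctl], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (anyDuplicated(signif(cuts, 12))) {
    abort(sprintf(
      "Degenerate quartile cut-points (ties): %s.",
      paste(signif(cuts, 6), collapse = ", ")
    ))
  }
  q <- cut(adj, c(-Inf, cuts, Inf), labels = c("Q1", "Q2", "Q3", "Q4"))
  d <- data
  d$.q2 <- as.numeric(q == "Q2")
  d$.q3 <- as.numeric(q == "Q3")
  d$.q4 <- as.numeric(q == "Q4")
  fit <- fit_clogit(d, c(".q2", ".q3", ".q4"), set = set, case = case)
  n_cases <- as.integer(table(q[data[[case]] == 1]))
  out <- tibble::tibble(
    quartile = c("Q1", "Q2", "Q3", "Q4"),
    n_cases = n_cases,
    or = c(1, exp(unname(fit$beta))),
    conf.low = c(NA_real_, exp(unname(fit$beta) - Z975 * unname(fit$se))),
    conf.high = c(NA_real_, exp(unname(fit$beta) + Z975 * unname(fit$se)))
  )
  attr(out, "fit") <- fit
  attr(out, "quartile") <- q
  out
}

#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator of repeatability: `(MSB - MSW) / (MSB + (k0 - 1) * MSW)`,
#' where MSB and MSW are the between- and within-group mean squares and `k0`
#' the (ANOVA-weighted) average group size; the 95% confidence interval uses
#' the F distribution.
#'
#' @param data A data frame of repeated measurements.
#' @param group Column identifying the measured image (bare name or string).
#' @param value Column of measurement values.
#' @return A one-row tibble: `icc`, `conf.low`, `conf.high`, `n_groups`,
#'   `k0`, `msb`, `msw`.
#' @examples
#' reps <- generate_repeat_measurements(50, 0.9, seed = 1)
#' icc(reps, pair_id, value)
#' @export
icc <- function(data, group, value) {
  g <- factor(dplyr::pull(data, {{ group }}))
  y <- as.numeric(dplyr::pull(data, {{ value }}))
  keep <- !is.na(y) & !is.na(g)
  g <- droplevels(g[keep])
  y <- y[keep]
  sizes <- as.integer(table(g))
  if (sum(sizes >= 2L) < 2L) {
    abort("At least two groups with two or more measurements are required.")
  }
  N <- length(y)
  a <- nlevels(g)
  gm <- tapply(y, g, mean)
  ssb <- sum(sizes * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(sizes^2) / N) / (a - 1)
  if (msw <= 0) { # exact duplicates within every group
    return(tibble::tibble(
      icc = 1, conf.low = 1, conf.high = 1,
      n_groups = a, k0 = k0, msb = msb, msw = msw
    ))
  }
  est <- (msb - msw) / (msb + (k0 - 1) * msw)
  f <- msb / msw
  fl <- f / qf(0.975, a - 1, N - a)
  fu <- f * qf(0.975, N - a, a - 1)
  tibble::tibble(
    icc = est,
    conf.low = (fl - 1) / (fl + k0 - 1),
    conf.high = (fu - 1) / (fu + k0 - 1),
    n_groups = a, k0 = k0, msb = msb, msw = msw
  )
}
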