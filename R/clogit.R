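#' Conditional log-likelihood of a matched-set logistic model
#'
#' Evaluates the conditional logistic log-likelihood
#' `sum_sets [eta_case - log(sum_members exp(eta))]` with `eta = X %*% beta`,
#' using log-sum-exp stabilization. Each set must contain exactly one case.
#'
#' @param data A data frame with one row per subject.
#' @param beta Numeric coefficient vector, one per term.
#' @param terms Character vector of covariate column names.
#' @param set,case Names of the matched-set id and case-indicator (0/1 or
#'   logical) columns.
#' @return The conditional log-likelihood (a scalar, always <= 0).
#' @examples
#' d <- data.frame(set_id = rep(1, 4), case = c(1, 0, 0, 0), x = c(1, 0, 0, 0))
#' conditional_loglik(d, log(3), "x") # log(3 / 6)
#' @export
conditional_loglik <- function(data, beta, terms, set = "set_id",
                               case = "case") {
  prep <- clogit_prepare(data, terms, set, case, drop_missing = FALSE)
  clogit_parts(prep$X, prep$g, prep$is_case, beta)$loglik
}

# validate columns, check the one-case-per-set invariant, optionally drop
# subjects with missing covariates (whole set if the case is missing)
clogit_prepare <- function(data, terms, set, case, drop_missing = TRUE,
                           quiet = FALSE) {
  for (col in c(terms, set, case)) {
    if (!col %in% names(data)) abort(paste0("Column not found: ", col))
  }
  if (anyDuplicated(terms)) abort("Duplicate model terms.")
  is_case <- as.logical(data[[case]])
  X <- as.matrix(data[terms])
  if (!is.numeric(X)) abort("Model terms must be numeric columns.")
  set_id <- data[[set]]

  n_dropped_subjects <- 0L
  n_dropped_sets <- 0L
  miss <- !stats::complete.cases(X) | is.na(is_case)
  if (any(miss)) {
    if (!drop_missing) abort("Missing values in model terms or case flag.")
    bad_sets <- unique(set_id[miss & is_case])
    keep <- !miss & !(set_id %in% bad_sets)
    n_dropped_subjects <- sum(!keep)
    n_dropped_sets <- length(bad_sets)
    if (!quiet) {
      inform(sprintf(
        "fit_clogit: dropped %d subject(s) with missing values (%d whole set(s) lost a case).",
        n_dropped_subjects, n_dropped_sets
      ))
    }
    X <- X[keep, , drop = FALSE]
    is_case <- is_case[keep]
    set_id <- set_id[keep]
  }
  f <- factor(set_id)
  g <- as.integer(f)
  cases_per_set <- tapply(is_case, g, sum)
  bad <- which(cases_per_set != 1L)
  if (length(bad)) {
    abort(paste0(
      "Each matched set must contain exactly one case; offending set(s): ",
      paste(utils::head(levels(f)[bad], 5L), collapse = ", ")
    ))
  }
  list(X = X, g = g, is_case = is_case, levels = levels(f),
       n_dropped_subjects = n_dropped_subjects, n_dropped_sets = n_dropped_sets)
}

# log-likelihood, score and observed information of the conditional logistic
# model at beta (log-sum-exp stabilized)
clogit_parts <- function(X, g, is_case, beta, want_derivs = TRUE) {
  eta <- drop(X %*% beta)
  mx <- as.vector(tapply(eta, g, max))
  w_raw <- exp(eta - mx[g])
  denom <- as.vector(rowsum(w_raw, g))
  loglik <- sum(eta[is_case]) - sum(mx + log(denom))
  if (!want_derivs) return(list(loglik = loglik))
  w <- w_raw / denom[g]
  wX <- w * X
  score <- colSums(X[is_case, , drop = FALSE]) - colSums(wX)
  S <- rowsum(wX, g)
  info <- crossprod(X, wX) - crossprod(S)
  list(loglik = loglik, score = score, info = info)
}

#' Fit conditional logistic regression to 1:M matched sets
#'
#' Newton-Raphson maximization of the conditional likelihood with analytic
#' score and observed information, step-halving on any likelihood decrease,
#' and convergence declared when the largest score component falls below
#' `tol`. Standard errors come from the inverse observed information and Wald
#' 95% confidence limits use `beta +/- 1.959964 * SE`. Subjects with missing
#' covariates are dropped (the whole set when its case is dropped); sets
#' violating the one-case rule are an error. An apparent separation (any
#' `|beta| > 10` on the standardized scale with a non-vanishing gradient) is
#' flagged as non-convergence.
#'
#' @inheritParams conditional_loglik
#' @param tol Convergence tolerance on the maximum absolute score component.
#' @param max_iter Maximum Newton iterations.
#' @param quiet Suppress the missing-data message.
#' @return An object of class `clogit_fit`: a list with `beta`, `cov`, `se`,
#'   `loglik`, `loglik_null` (all coefficients zero), `n_sets`, `n_subjects`,
#'   `converged`, `iterations`, and the dropped-row accounting. Methods:
#'   [tidy()], [glance()], `print()`.
#' @examples
#' cohort <- generate_matched_sets(sim_params(n_sets_screen = 0, seed = 1),
#'                                 keep_latent = TRUE)
#' fit <- fit_clogit(cohort, ".z_cumulus_pct")
#' tidy(fit)
#' @export
fit_clogit <- function(data, terms, set = "set_id", case = "case",
                       tol = 1e-8, max_iter = 50L, quiet = FALSE) {
  prep <- clogit_prepare(data, terms, set, case, quiet = quiet)
  X <- prep$X
  g <- prep$g
  is_case <- prep$is_case
  n_sets <- length(unique(g))
  if (n_sets < 1L) abort("No matched sets left to fit.")

  # informative sets have within-set variation in at least one term
  informative <- any(vapply(seq_len(ncol(X)), function(j) {
    any(vapply(split(X[, j], g), function(v) diff(range(v)) > 0, logical(1)))
  }, logical(1)))
  if (!informative) {
    abort("No informative sets: no within-set variation in any model term.")
  }

  p <- ncol(X)
  beta <- rep(0, p)
  parts <- clogit_parts(X, g, is_case, beta)
  loglik_null <- parts$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(parts$score)) < tol) {
      converged <- TRUE
      break
    }
    dir <- tryCatch(solve(parts$info, parts$score), error = function(e) {
      abort(paste0("Singular information matrix: ", conditionMessage(e)))
    })
    step <- 1
    for (h in seq_len(10L)) {
      cand <- beta + step * dir
      cand_parts <- clogit_parts(X, g, is_case, cand)
      if (cand_parts$loglik >= parts$loglik - 1e-10) break
      step <- step / 2
    }
    beta <- cand
    parts <- cand_parts
  }
  if (!converged && max(abs(parts$score)) < tol) converged <- TRUE
  if (any(abs(beta) > 10) && !converged) {
    warn("Possible separation: |beta| > 10 with a non-vanishing gradient; fit flagged as non-converged.")
  } else if (!converged) {
    warn(sprintf("fit_clogit did not converge in %d iterations.", max_iter))
  }
  cov <- solve(parts$info)
  cov <- (cov + t(cov)) / 2
  names(beta) <- terms
  dimnames(cov) <- list(terms, terms)
  structure(
    list(
      beta = beta,
      cov = cov,
      se = sqrt(diag(cov)),
      loglik = parts$loglik,
      loglik_null = loglik_null,
      n_sets = n_sets,
      n_subjects = nrow(X),
      n_dropped_subjects = prep$n_dropped_subjects,
      n_dropped_sets = prep$n_dropped_sets,
      converged = converged,
      iterations = iter,
      terms = terms,
      max_score = max(abs(parts$score))
    ),
    class = "clogit_fit"
  )
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf(
    "<clogit_fit> %d set(s), %d subject(s), logLik %.4f (null %.4f), %s in %d iteration(s)\n",
    x$n_sets, x$n_subjects, x$loglik, x$loglik_null,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  print(tidy(x))
  invisible(x)
}

#' Likelihood-ratio test of nested conditional logistic fits
#'
#' Computes `2 * (logLik_full - logLik_reduced)` with a chi-squared reference
#' on the difference in term counts. The reduced model's terms must be a
#' subset of the full model's, fitted to the same sets.
#'
#' @param fit_full,fit_reduced `clogit_fit` objects from [fit_clogit()].
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `loglik_full`,
#'   `loglik_reduced`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "clogit_fit"), inherits(fit_reduced, "clogit_fit"))
  if (!all(fit_reduced$terms %in% fit_full$terms)) {
    abort("Models are not nested: reduced terms are not a subset of full terms.")
  }
  if (fit_full$n_sets != fit_reduced$n_sets ||
      fit_full$n_subjects != fit_reduced$n_subjects) {
    abort("Fits use different data (set or subject counts differ).")
  }
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-6) {
    abort("Full-model log-likelihood is below the reduced model's; fits are inconsistent.")
  }
  stat <- max(stat, 0)
  df <- length(fit_full$terms) - length(fit_reduced$terms)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(
    statistic = stat, df = df, p.value = p,
    loglik_full = fit_full$loglik, loglik_reduced = fit_reduced$loglik
  )
}

#' Unconditional logistic regression for case-subgroup contrasts
#'
#' Ordinary maximum-likelihood logistic regression (via [stats::glm()]),
#' used to compare independent sub-groups of cases, e.g. interval versus
#' screen-detected disease. Apparent separation is flagged as
#' non-convergence.
#'
#' @param data A data frame of subjects.
#' @param terms Character vector of covariate column names.
#' @param outcome Name of the binary outcome column (0/1, logical, or a
#'   two-level factor/character; the second level is the event).
#' @return An object of class `ulogit_fit` with `beta`, `cov`, `se`,
#'   `loglik`, `converged`, `n`; methods [tidy()] and [glance()].
#' @export
fit_unconditional_logit <- function(data, terms, outcome) {
  for (col in c(terms, outcome)) {
    if (!col %in% names(data)) abort(paste0("Column not found: ", col))
  }
  y <- data[[outcome]]
  if (is.character(y) || is.factor(y)) {
    y <- factor(y)
    if (nlevels(y) != 2L) abort("`outcome` must have exactly two levels.")
    y <- as.integer(y) - 1L
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`outcome` must be binary.")
  df <- data.frame(.y = y, data[terms], check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", terms), response = ".y")
  fit <- glm(fml, family = binomial(), data = df)
  beta <- coef(fit)[-1L]
  names(beta) <- terms
  cov <- vcov(fit)[-1L, -1L, drop = FALSE]
  dimnames(cov) <- list(terms, terms)
  converged <- fit$converged && all(abs(coef(fit)) <= 10)
  if (!converged) warn("Possible separation or non-convergence in unconditional logistic fit.")
  structure(
    list(
      beta = beta, cov = cov, se = sqrt(diag(cov)),
      intercept = unname(coef(fit)[1L]),
      loglik = as.numeric(logLik(fit)),
      converged = converged,
      n = nrow(df),
      terms = terms,
      glm = fit
    ),
    class = "ulogit_fit"
  )
}

#' @export
print.ulogit_fit <- function(x, ...) {
  cat(sprintf(
    "<ulogit_fit> n = %d, logLik %.4f, %s\n",
    x$n, x$loglik, if (x$converged) "converged" else "NOT converged"
  ))
  print(tidy(x))
  invisible(x)
}
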