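#' Covariate-adjust and standardize a transformed density measure
#'
#' Regresses the transformed measure on age and BMI among controls only
#' (ordinary least squares), computes residuals for all subjects with the
#' control-fitted coefficients, and divides by the adjusted standard
#' deviation -- the SD of the control residuals (n - 1 denominator). The
#' control subset of the output therefore has SD exactly 1, which is the
#' scale on which the odds ratio per adjusted standard deviation (OPERA) is
#' defined. Using control-only coefficients for everyone avoids leaking case
#' status into the adjustment.
#'
#' @param transformed Numeric vector of transformed measure values.
#' @param age,bmi Numeric covariate vectors, same length.
#' @param control_flag Logical (or 0/1) vector: `TRUE` for controls.
#' @param lambda Optional Box-Cox lambda to record alongside the result.
#' @return An object of class `adjusted_measure`: a list with
#'   `values_standardized`, `coefficients` (intercept, age, bmi),
#'   `sd_unadjusted` (SD of transformed controls), `sd_adjusted` (SD of
#'   control residuals, always <= `sd_unadjusted`), `lambda`, `n_controls`.
#' @export
adjust_and_standardize <- function(transformed, age, bmi, control_flag,
                                   lambda = NA_real_) {
  n <- length(transformed)
  if (length(age) != n || length(bmi) != n || length(control_flag) != n) {
    abort("`transformed`, `age`, `bmi` and `control_flag` must have equal length.")
  }
  if (anyNA(transformed) || anyNA(age) || anyNA(bmi)) {
    abort("Missing values must be excluded upstream.")
  }
  ctl <- as.logical(control_flag)
  if (sum(ctl) < 3L) abort("At least 3 controls are required for adjustment.")

  Xc <- cbind(1, age = age[ctl], bmi = bmi[ctl])
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    abort(sprintf(
      "Collinear covariates: design matrix rank %d < %d columns.",
      qrX$rank, ncol(Xc)
    ))
  }
  coefs <- qr.coef(qrX, transformed[ctl])
  fitted_all <- drop(cbind(1, age, bmi) %*% coefs)
  resid_all <- transformed - fitted_all
  sd_unadjusted <- sd(transformed[ctl])
  sd_adjusted <- sd(resid_all[ctl])
  if (sd_adjusted < 1e-10) {
    abort("Zero adjusted SD: the measure is an exact function of age and BMI among controls.")
  }
  structure(
    list(
      values_standardized = resid_all / sd_adjusted,
      coefficients = setNames(as.numeric(coefs), c("intercept", "age", "bmi")),
      sd_unadjusted = sd_unadjusted,
      sd_adjusted = sd_adjusted,
      lambda = lambda,
      n_controls = sum(ctl)
    ),
    class = "adjusted_measure"
  )
}

#' @export
print.adjusted_measure <- function(x, ...) {
  cat(sprintf(
    "<adjusted_measure> n = %d (%d controls), lambda = %s, SD %.4f -> adjusted %.4f\n",
    length(x$values_standardized), x$n_controls,
    ifelse(is.na(x$lambda), "NA", sprintf("%.3f", x$lambda)),
    x$sd_unadjusted, x$sd_adjusted
  ))
  invisible(x)
}

#' Average standardized measures across measurers
#'
#' Element-wise mean of per-measurer standardized values for the same
#' subjects, re-reported with the control SD of the average (below 1 when
#' measurers are imperfectly correlated: for `k` equicorrelated unit-variance
#' measurers with pairwise correlation `r`, the SD is
#' `sqrt((1 + (k - 1) r) / k)`).
#'
#' @param standardized_per_measurer A list of numeric vectors (or
#'   `adjusted_measure` objects) of identical length, one per measurer.
#' @param control_flag Logical vector marking controls, used for the
#'   re-reported SD.
#' @return A list with `values` (the per-subject average) and `sd_control`
#'   (control SD of the average).
#' @export
average_measurers <- function(standardized_per_measurer, control_flag) {
  vals <- purrr::map(standardized_per_measurer, function(v) {
    if (inherits(v, "adjusted_measure")) v$values_standardized else as.numeric(v)
  })
  lens <- purrr::map_int(vals, length)
  if (length(unique(lens)) != 1L || lens[1] != length(control_flag)) {
    abort("All measurers must report the same subjects (equal-length vectors).")
  }
  avg <- purrr::reduce(vals, `+`) / length(vals)
  list(values = avg, sd_control = sd(avg[as.logical(control_flag)]))
}

#' Transform, adjust and standardize every density measure of a cohort
#'
#' For each requested measure: estimates the Box-Cox lambda by maximum
#' likelihood on controls, transforms all subjects, adjusts for age and BMI
#' with control-fitted OLS coefficients, and scales by the adjusted SD
#' (see [adjust_and_standardize()]). Standardization is done separately
#' within each outcome mode by default, mirroring analyses that use each
#' outcome's own controls. Standardized values are appended as
#' `<measure>_std` columns and the per-measure adjustment report (lambda,
#' shift, coefficients, SDs) is attached as the `"standardization"`
#' attribute and returned by [standardization_report()].
#'
#' @param cohort A cohort tibble (see [generate_matched_sets()]).
#' @param measures Character vector of measure columns (default all six).
#' @param by_mode Standardize within each `mode` level separately (default
#'   `TRUE`; set `FALSE` to pool).
#' @return The cohort with `<measure>_std` columns added and a
#'   `"standardization"` attribute.
#' @examples
#' cohort <- generate_matched_sets(sim_params(n_sets_screen = 0, seed = 1))
#' std <- standardize_cohort(cohort)
#' standardization_report(std)
#' @export
standardize_cohort <- function(cohort, measures = density_measures(),
                               by_mode = TRUE) {
  groups <- if (by_mode && "mode" %in% names(cohort)) {
    split(seq_len(nrow(cohort)), cohort$mode)
  } else {
    list(all = seq_len(nrow(cohort)))
  }
  report <- list()
  for (msr in measures) {
    if (!msr %in% names(cohort)) abort(paste0("Measure column not found: ", msr))
    std <- rep(NA_real_, nrow(cohort))
    for (gname in names(groups)) {
      idx <- groups[[gname]]
      y <- cohort[[msr]][idx]
      ctl <- cohort$case[idx] == 0
      bc <- suppressMessages(boxcox_lambda_mle(y[ctl]))
      transformed <- boxcox_transform(y, bc$lambda, bc$shift)
      adj <- adjust_and_standardize(
        transformed, cohort$age[idx], cohort$bmi[idx], ctl,
        lambda = bc$lambda
      )
      std[idx] <- adj$values_standardized
      report[[length(report) + 1L]] <- tibble::tibble(
        measure = msr, group = gname,
        lambda = bc$lambda, shift = bc$shift,
        intercept = adj$coefficients[["intercept"]],
        age = adj$coefficients[["age"]],
        bmi = adj$coefficients[["bmi"]],
        sd_unadjusted = adj$sd_unadjusted,
        sd_adjusted = adj$sd_adjusted,
        n = length(idx), n_controls = adj$n_controls
      )
    }
    cohort[[paste0(msr, "_std")]] <- std
  }
  attr(cohort, "standardization") <- dplyr::bind_rows(report)
  cohort
}

#' @rdname standardize_cohort
#' @param standardized A cohort returned by `standardize_cohort()`.
#' @export
standardization_report <- function(standardized) {
  rep <- attr(standardized, "standardization")
  if (is.null(rep)) abort("No standardization report: run standardize_cohort() first.")
  rep
}

#' Write the adjustment report as structured text
#'
#' @param standardized A cohort returned by [standardize_cohort()].
#' @param path Output file path.
#' @return The report tibble, invisibly.
#' @export
write_standardization_report <- function(standardized, path) {
  rep <- standardization_report(standardized)
  readr::write_csv(rep, path, progress = FALSE)
  invisible(rep)
}
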