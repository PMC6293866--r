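#' Canonical density-measure column names
#'
#' The six density measures, in cohort column order: dense area (`_da`, cm^2)
#' and percent density (`_pct`, %) at each of the three brightness thresholds
#' (conventional `cumulus`, higher `alto`, highest `cirro`).
#'
#' @return Character vector of length six.
#' @export
density_measures <- function() {
  c("cumulus_da", "cumulus_pct", "alto_da", "alto_pct", "cirro_da", "cirro_pct")
}

#' Default latent correlation matrix for the six density measures
#'
#' Inter-measure correlations of the transformed, adjusted, standardized
#' measures: 0.86 (conventional vs higher threshold, dense area), 0.88 (same,
#' percent), 0.82 for all pairs involving the highest threshold and for
#' cross-scale pairs, and within-threshold dense-area/percent correlations of
#' 0.87, 0.92 and 0.96 for the three thresholds respectively.
#'
#' @return A symmetric positive-definite 6x6 matrix with unit diagonal, rows
#'   and columns named as [density_measures()].
#' @export
default_density_corr <- function() {
  nm <- density_measures()
  m <- matrix(0.82, 6L, 6L, dimnames = list(nm, nm))
  diag(m) <- 1
  set2 <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set2("cumulus_da", "alto_da", 0.86)
  set2("cumulus_pct", "alto_pct", 0.88)
  set2("cumulus_da", "cumulus_pct", 0.87)
  set2("alto_da", "alto_pct", 0.92)
  set2("cirro_da", "cirro_pct", 0.96)
  m
}

#' Simulation parameters for the synthetic nested case-control cohort
#'
#' Bundles every knob of the cohort generator: set counts and matching ratio,
#' the 6x6 latent correlation of the density measures, per-outcome log-odds
#' per adjusted standard deviation, the screen-mode BMI-by-age interaction,
#' covariate distributions, the raw-scale marginal moments and Box-Cox shape
#' used to back-transform latent traits to cm^2 / percent, and the
#' repeatability ICC. Defaults reproduce the structure of a two-yearly
#' screening cohort: 168 interval-cancer sets and 422 screen-detected sets at
#' 1 case : 3 controls, age about N(56.2, 6.8^2) (interval) or N(58.4, 7.6^2)
#' (screen), BMI about N(26.5, 4.9^2) truncated at 15, live births
#' Poisson(2.7) truncated to 0-8, and raw density moments matching typical
#' film-mammogram values (e.g. conventional dense area 19 (SD 11) cm^2 among
#' controls).
#'
#' `beta_interval` / `beta_screen` are named vectors of log-odds per adjusted
#' SD, names drawn from [density_measures()]; measures not named carry zero
#' effect. The default generating mechanism has percent density at the
#' conventional threshold driving interval cancer (log-odds 0.85) and dense
#' area at the highest threshold driving screen-detected cancer (log-odds
#' 0.28), plus a small positive BMI-by-age interaction for screen-detected
#' disease.
#'
#' @param n_sets_interval,n_sets_screen Number of matched sets per outcome.
#' @param controls_per_case Controls per case (M in 1:M matching), >= 1.
#' @param corr_matrix 6x6 latent correlation matrix; see
#'   [default_density_corr()].
#' @param beta_interval,beta_screen Named numeric vectors: log-odds per
#'   adjusted SD of each standardized measure, by outcome.
#' @param bmi_age_interaction_screen Log-odds per unit of centered
#'   (BMI - mean BMI) x (age - mean age), applied in screen-detected sets.
#' @param age_mean,age_sd Named numeric (interval, screen): age at mammogram
#'   distribution in years.
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2 (truncated at 15).
#' @param livebirths_mean Mean of the truncated Poisson live-birth count.
#' @param boxcox_lambda_true Box-Cox shape used to back-transform latent
#'   traits to the raw scale (0 = log-normal raw measures).
#' @param raw_mean,raw_sd Named numeric vectors (names =
#'   [density_measures()]): raw-scale marginal mean and SD targets.
#' @param age_coef,bmi_coef Named numeric vectors: linear dependence of each
#'   transformed measure on centered age (per year) and BMI (per kg/m^2),
#'   giving the confounding that the adjustment step later removes.
#' @param icc_true Repeatability intraclass correlation in \[0, 1\].
#' @param family_history_prob Prevalence of positive family history
#'   (descriptive only; carries no risk in the generator).
#' @param seed Optional integer master seed stored with the parameters.
#'
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(n_sets_interval = 20, n_sets_screen = 0, seed = 1)
#' cohort <- generate_matched_sets(p)
#' dplyr::count(cohort, case)
#' @export
sim_params <- function(n_sets_interval = 168L,
                       n_sets_screen = 422L,
                       controls_per_case = 3L,
                       corr_matrix = default_density_corr(),
                       beta_interval = c(cumulus_pct = 0.85),
                       beta_screen = c(cirro_da = 0.28),
                       bmi_age_interaction_screen = 0.004,
                       age_mean = c(interval = 56.2, screen = 58.4),
                       age_sd = c(interval = 6.8, screen = 7.6),
                       bmi_mean = 26.5,
                       bmi_sd = 4.9,
                       livebirths_mean = 2.7,
                       boxcox_lambda_true = 0,
                       raw_mean = c(cumulus_da = 19, cumulus_pct = 14.5,
                                    alto_da = 9, alto_pct = 7,
                                    cirro_da = 4, cirro_pct = 3),
                       raw_sd = c(cumulus_da = 11, cumulus_pct = 9,
                                  alto_da = 7, alto_pct = 6,
                                  cirro_da = 4.8, cirro_pct = 3.5),
                       age_coef = setNames(rep(-0.02, 6), density_measures()),
                       bmi_coef = c(cumulus_da = -0.02, cumulus_pct = -0.08,
                                    alto_da = -0.02, alto_pct = -0.08,
                                    cirro_da = -0.02, cirro_pct = -0.08),
                       icc_true = 0.95,
                       family_history_prob = 0.15,
                       seed = NULL) {
  nm <- density_measures()
  check_corr_matrix(corr_matrix)
  if (controls_per_case < 1) {
    abort("`controls_per_case` must be at least 1.")
  }
  if (icc_true < 0 || icc_true > 1) {
    abort("`icc_true` must lie in [0, 1].")
  }
  raw_mean <- raw_mean[nm]
  raw_sd <- raw_sd[nm]
  if (anyNA(raw_mean) || anyNA(raw_sd)) {
    abort("`raw_mean` and `raw_sd` must name all six density measures.")
  }
  if (any(raw_sd <= 0)) abort("raw-scale SDs must be positive.")
  for (b in list(beta_interval, beta_screen)) {
    bad <- setdiff(names(b), nm)
    if (length(bad)) {
      abort(paste0("Unknown measure in beta vector: ", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      n_sets_interval = as.integer(n_sets_interval),
      n_sets_screen = as.integer(n_sets_screen),
      controls_per_case = as.integer(controls_per_case),
      corr_matrix = corr_matrix,
      beta_interval = beta_interval,
      beta_screen = beta_screen,
      bmi_age_interaction_screen = bmi_age_interaction_screen,
      age_mean = age_mean, age_sd = age_sd,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      livebirths_mean = livebirths_mean,
      boxcox_lambda_true = boxcox_lambda_true,
      raw_mean = raw_mean, raw_sd = raw_sd,
      age_coef = age_coef[nm], bmi_coef = bmi_coef[nm],
      icc_true = icc_true,
      family_history_prob = family_history_prob,
      seed = seed
    ),
    class = "sim_params"
  )
}

check_corr_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Correlation matrix must be square.")
  }
  if (max(abs(m - t(m))) > tol) abort("Correlation matrix must be symmetric.")
  if (max(abs(diag(m) - 1)) > tol) {
    abort("Correlation matrix must have unit diagonal.")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf(
      "Correlation matrix is not positive semi-definite: smallest eigenvalue %.3g.",
      min(ev)
    ))
  }
  invisible(m)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf(
    "  sets: %d interval + %d screen, 1:%d matching\n",
    x$n_sets_interval, x$n_sets_screen, x$controls_per_case
  ))
  fmt_beta <- function(b) {
    if (!length(b)) return("none")
    paste(sprintf("%s=%.3g", names(b), b), collapse = ", ")
  }
  cat("  log-odds/SD interval:", fmt_beta(x$beta_interval), "\n")
  cat("  log-odds/SD screen:  ", fmt_beta(x$beta_screen), "\n")
  cat(sprintf(
    "  BMIxage interaction (screen): %.3g; lambda_true: %.3g; ICC: %.3g\n",
    x$bmi_age_interaction_screen, x$boxcox_lambda_true, x$icc_true
  ))
  invisible(x)
}
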