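#' Generate a synthetic nested case-control cohort of matched sets
#'
#' Draws matched 1 case : M control sets under an exact conditional-logistic
#' data-generating mechanism. For each set, `controls_per_case + 1` candidate
#' women sharing the matching variable (birth-year stratum) are simulated:
#' correlated standard-normal latent traits represent the transformed,
#' covariate-adjusted, standardized density measures; raw-scale dense areas
#' and percent densities are obtained by adding linear age/BMI confounding on
#' the transformed scale and inverting the Box-Cox transform. The case is then
#' designated by a single multinomial draw with within-set probability
#' `exp(eta_j) / sum_k exp(eta_k)`, where
#' `eta = sum(beta * z) + interaction` (the centered BMI-by-age product term
#' applies in screen-detected sets), which is exactly the conditional-logistic
#' likelihood, so fitting the generated data recovers the generating
#' log-odds.
#'
#' Dense areas (and percent densities) are nested across thresholds in every
#' record; the rare draws violating the ordering implied by the marginal
#' moments are restored by an order-preserving clamp whose count is reported.
#'
#' @param params A [sim_params()] object.
#' @param mode Which outcome strata to generate: `"both"` (default),
#'   `"interval"` or `"screen"`.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param keep_latent Also return the latent standardized traits as
#'   `.z_<measure>` columns (useful for calibration studies).
#' @param quiet Suppress the clamp-count message.
#' @return A tibble with one row per woman: `set_id`, `subject_id`, `case`
#'   (0/1, exactly one per set), `mode`, `age` (years), `bmi` (kg/m^2),
#'   `livebirths`, `family_history` (0/1), the six density columns of
#'   [density_measures()] (cm^2 / percent), and the matching variable
#'   `birth_year`. Attributes: `params`, `n_nesting_clamped`,
#'   `n_backtransform_clamped`.
#' @examples
#' cohort <- generate_matched_sets(sim_params(seed = 1), mode = "interval")
#' dplyr::count(cohort, mode, case)
#' @export
generate_matched_sets <- function(params,
                                  mode = c("both", "interval", "screen"),
                                  seed = params$seed,
                                  keep_latent = FALSE,
                                  quiet = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("interval", "screen") else mode
  out <- with_seed(seed, {
    purrr::map(modes, function(m) generate_mode_stratum(params, m, keep_latent))
  })
  cohort <- dplyr::bind_rows(purrr::map(out, "data"))
  n_nest <- sum(purrr::map_int(out, "n_nesting_clamped"))
  n_bt <- sum(purrr::map_int(out, "n_backtransform_clamped"))
  if (!quiet && (n_nest > 0L || n_bt > 0L)) {
    inform(sprintf(
      "generate_matched_sets: %d nesting clamp(s), %d back-transform floor clamp(s) in %d records.",
      n_nest, n_bt, nrow(cohort)
    ))
  }
  attr(cohort, "params") <- params
  attr(cohort, "n_nesting_clamped") <- n_nest
  attr(cohort, "n_backtransform_clamped") <- n_bt
  cohort
}

# one outcome stratum (interval or screen): simulate candidates and pick the
# case by the within-set softmax of the linear predictor
generate_mode_stratum <- function(params, m, keep_latent) {
  n_sets <- if (m == "interval") params$n_sets_interval else params$n_sets_screen
  if (n_sets < 1L) {
    return(list(data = NULL, n_nesting_clamped = 0L, n_backtransform_clamped = 0L))
  }
  msize <- params$controls_per_case + 1L
  n <- n_sets * msize
  nm <- density_measures()

  set_idx <- rep(seq_len(n_sets), each = msize)
  set_age <- rnorm(n_sets, params$age_mean[[m]], params$age_sd[[m]])
  birth_year <- 1992L - as.integer(round(set_age))
  age <- set_age[set_idx] + rnorm(n, 0, 1)
  bmi <- rnorm(n, params$bmi_mean, params$bmi_sd)
  while (any(low <- bmi < 15)) { # truncate BMI at 15 by rejection
    bmi[low] <- rnorm(sum(low), params$bmi_mean, params$bmi_sd)
  }
  livebirths <- pmin(rpois(n, params$livebirths_mean), 8L)
  family_history <- rbinom(n, 1L, params$family_history_prob)

  z <- generate_latent_traits(n, params$corr_matrix)
  n_bt <- 0L
  raw <- matrix(NA_real_, n, 6L, dimnames = list(NULL, nm))
  for (j in nm) {
    # confounding on the transformed scale, then rescale to unit SD so the
    # raw-scale marginal moments still match their targets
    t_j <- z[, j] +
      params$age_coef[[j]] * (age - params$age_mean[[m]]) +
      params$bmi_coef[[j]] * (bmi - params$bmi_mean)
    tot_sd <- sqrt(1 + (params$age_coef[[j]] * params$age_sd[[m]])^2 +
                     (params$bmi_coef[[j]] * params$bmi_sd)^2)
    bt <- backtransform_to_raw(
      t_j / tot_sd, params$boxcox_lambda_true,
      params$raw_mean[[j]], params$raw_sd[[j]],
      quiet = TRUE
    )
    n_bt <- n_bt + (attr(bt, "n_clamped") %||% 0L)
    raw[, j] <- as.numeric(bt)
  }
  raw[, c("cumulus_pct", "alto_pct", "cirro_pct")] <-
    pmin(raw[, c("cumulus_pct", "alto_pct", "cirro_pct")], 100)

  # enforce nesting across thresholds: conventional >= higher >= highest
  before <- raw
  raw[, "alto_da"] <- pmin(raw[, "alto_da"], raw[, "cumulus_da"])
  raw[, "cirro_da"] <- pmin(raw[, "cirro_da"], raw[, "alto_da"])
  raw[, "alto_pct"] <- pmin(raw[, "alto_pct"], raw[, "cumulus_pct"])
  raw[, "cirro_pct"] <- pmin(raw[, "cirro_pct"], raw[, "alto_pct"])
  n_nest <- sum(raw != before)

  beta <- if (m == "interval") params$beta_interval else params$beta_screen
  eta <- rep(0, n)
  for (j in names(beta)) eta <- eta + beta[[j]] * z[, j]
  if (m == "screen" && params$bmi_age_interaction_screen != 0) {
    eta <- eta + params$bmi_age_interaction_screen *
      (bmi - params$bmi_mean) * (age - params$age_mean[[m]])
  }

  # one multinomial draw per set with probabilities softmax(eta)
  eta_m <- matrix(eta, nrow = n_sets, ncol = msize, byrow = TRUE)
  w <- exp(eta_m - apply(eta_m, 1L, max))
  cum <- w
  for (k in seq_len(msize)[-1L]) cum[, k] <- cum[, k - 1L] + w[, k]
  u <- runif(n_sets) * cum[, msize]
  case_pos <- rowSums(cum < u) + 1L
  case <- integer(n)
  case[(seq_len(n_sets) - 1L) * msize + case_pos] <- 1L

  prefix <- if (m == "interval") "I" else "S"
  data <- tibble::tibble(
    set_id = sprintf("%s%04d", prefix, set_idx),
    subject_id = sprintf("%s%04d-%d", prefix, set_idx,
                         rep(seq_len(msize), times = n_sets)),
    case = case,
    mode = m,
    age = age,
    bmi = bmi,
    livebirths = as.integer(livebirths),
    family_history = as.integer(family_history)
  )
  for (j in nm) data[[j]] <- as.numeric(raw[, j])
  data$birth_year <- birth_year[set_idx]
  if (keep_latent) {
    for (j in nm) data[[paste0(".z_", j)]] <- as.numeric(z[, j])
  }
  list(data = data, n_nesting_clamped = n_nest, n_backtransform_clamped = n_bt)
}

#' Generate repeated density measurements with known repeatability
#'
#' Simulates pairs (or longer runs) of repeated measurements of the same
#' image as `y = t + e`, with the true-score variance fraction
#' `Var(t) / (Var(t) + Var(e))` equal to `icc_true`; both members of a pair
#' share `t`. Total variance is 1.
#'
#' @param n_pairs Number of measured images (groups).
#' @param icc_true True intraclass correlation in \[0, 1\].
#' @param seed Optional integer seed.
#' @param n_repeats Measurements per image (default 2).
#' @return A tibble with columns `pair_id`, `replicate`, `value`.
#' @examples
#' reps <- generate_repeat_measurements(180, icc_true = 0.95, seed = 1)
#' icc(reps, pair_id, value)$icc
#' @export
generate_repeat_measurements <- function(n_pairs, icc_true, seed = NULL,
                                         n_repeats = 2L) {
  if (icc_true < 0 || icc_true > 1) abort("`icc_true` must lie in [0, 1].")
  stopifnot(n_pairs >= 1, n_repeats >= 2)
  with_seed(seed, {
    t_i <- rnorm(n_pairs, 0, sqrt(icc_true))
    e <- rnorm(n_pairs * n_repeats, 0, sqrt(1 - icc_true))
    tibble::tibble(
      pair_id = rep(seq_len(n_pairs), each = n_repeats),
      replicate = rep(seq_len(n_repeats), times = n_pairs),
      value = rep(t_i, each = n_repeats) + e
    )
  })
}

cohort_columns <- function() {
  c("set_id", "subject_id", "case", "mode", "age", "bmi", "livebirths",
    "family_history", density_measures(), "birth_year")
}

#' Read and write cohort CSV files
#'
#' `write_cohort()` writes the cohort tibble with a stable column order;
#' `read_cohort()` reads it back losslessly, reporting malformed rows with
#' their line numbers.
#'
#' @param cohort A cohort tibble (see [generate_matched_sets()]).
#' @param path File path of the cohort CSV.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `cohort` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(cohort), cohort_columns())
  readr::write_csv(cohort[c(cohort_columns(), extra)], path, progress = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spec <- readr::cols(
    set_id = readr::col_character(),
    subject_id = readr::col_character(),
    case = readr::col_integer(),
    mode = readr::col_character(),
    age = readr::col_double(),
    bmi = readr::col_double(),
    livebirths = readr::col_integer(),
    family_history = readr::col_integer(),
    birth_year = readr::col_integer(),
    .default = readr::col_double()
  )
  cohort <- readr::read_csv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Malformed cohort rows at line(s): ",
      paste(unique(probs$row), collapse = ", ")
    ))
  }
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cohort
}
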