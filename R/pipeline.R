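#' Configuration for the density model grid
#'
#' @param outcomes Outcome strata to analyse (`"interval"`, `"screen"`).
#' @param scales Measurement scales: `"dense_area"` and/or `"percent"`.
#' @param bic_convention Posterior-odds convention for [delta_bic()].
#' @param include_bmi Include centered BMI as a covariate in every model.
#' @param interaction_screen Add the centered BMI-by-age product term in
#'   screen-detected models (interval models keep the BMI main effect only).
#' @param quartile_covariates Covariates defining quartile cut-points in
#'   [quartile_ors()].
#' @param seed Seed recorded in the run manifest.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(outcomes = c("interval", "screen"),
                            scales = c("dense_area", "percent"),
                            bic_convention = c("paper", "halved"),
                            include_bmi = TRUE,
                            interaction_screen = TRUE,
                            quartile_covariates = c("age", "bmi", "livebirths"),
                            seed = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  scales <- match.arg(scales, several.ok = TRUE)
  if (!length(outcomes)) abort("At least one outcome is required.")
  structure(
    list(
      outcomes = outcomes, scales = scales,
      bic_convention = match.arg(bic_convention),
      include_bmi = include_bmi,
      interaction_screen = interaction_screen,
      quartile_covariates = quartile_covariates,
      seed = seed
    ),
    class = "analysis_config"
  )
}

measure_column <- function(measure, scale) {
  suffix <- if (scale == "dense_area") "_da" else "_pct"
  paste0(measure, suffix, "_std")
}

grid_measures <- function() c("cumulus", "alto", "cirro")

# the four multivariable models: all pairs plus the trivariable fit
grid_models <- function() {
  list(
    `1` = c("cumulus", "alto"),
    `2` = c("cumulus", "cirro"),
    `3` = c("alto", "cirro"),
    `4` = c("cumulus", "alto", "cirro")
  )
}

#' Fit the univariable / bivariable / trivariable model grid
#'
#' For each requested outcome and scale: fits each standardized measure
#' alone (OPERA, covariate-adjusted AUC, log-likelihood), the three pairwise
#' models and the trivariable model (per-term OPERAs rescaled by
#' `sqrt(1 - r^2)` against the other fitted measures, see
#' [bivariable_opera()]), likelihood-ratio tests of every nested addition,
#' and BIC comparisons among equal-parameter models (between measures within
#' a scale and between scales for the same measure). Models include centered
#' BMI, plus the centered BMI-by-age product for screen-detected sets.
#'
#' @param cohort A standardized cohort from [standardize_cohort()].
#' @param config An [analysis_config()].
#' @return An object of class `opera_grid`: a list of tibbles
#'   `univariable`, `multivariable`, `lrt`, `bic`, plus the `config`.
#' @examples
#' \donttest{
#' cohort <- standardize_cohort(generate_matched_sets(sim_params(seed = 1)))
#' grid <- run_model_grid(cohort, analysis_config())
#' grid$univariable
#' }
#' @export
run_model_grid <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  uni <- list()
  multi <- list()
  lrt <- list()
  bic <- list()

  for (o in config$outcomes) {
    d <- dplyr::filter(cohort, .data$mode == o)
    if (nrow(d) == 0L) abort(paste0("Outcome has zero sets: ", o))
    ctl <- d$case == 0
    d$.bmi_c <- d$bmi - mean(d$bmi[ctl])
    adj_terms <- character()
    if (config$include_bmi) adj_terms <- ".bmi_c"
    if (o == "screen" && config$interaction_screen) {
      d$.bmi_age <- (d$bmi - mean(d$bmi[ctl])) * (d$age - mean(d$age[ctl]))
      adj_terms <- c(adj_terms, ".bmi_age")
    }

    for (s in config$scales) {
      cols <- setNames(measure_column(grid_measures(), s), grid_measures())
      missing_cols <- setdiff(cols, names(d))
      if (length(missing_cols)) {
        abort(paste0("Standardized column(s) missing: ",
                     paste(missing_cols, collapse = ", "),
                     "; run standardize_cohort() first."))
      }

      uni_fits <- list()
      for (m in grid_measures()) {
        fit <- fit_clogit(d, c(cols[[m]], adj_terms), quiet = TRUE)
        uni_fits[[m]] <- fit
        op <- opera_from_fit(fit, cols[[m]])
        auc_res <- auc_adjusted(d[[cols[[m]]]], d$case)
        uni[[length(uni) + 1L]] <- tibble::tibble(
          outcome = o, scale = s, measure = m,
          log_opera = op$log_opera, se = op$se, opera = op$opera,
          conf.low = op$conf.low, conf.high = op$conf.high, iqrr = op$iqrr,
          p.value = 2 * pnorm(-abs(op$log_opera / op$se)),
          auc = auc_res$auc, auc_low = auc_res$conf.low,
          auc_high = auc_res$conf.high,
          loglik = fit$loglik, loglik_null = fit$loglik_null,
          n_sets = fit$n_sets, converged = fit$converged
        )
      }

      multi_fits <- list()
      for (mid in names(grid_models())) {
        mm <- grid_models()[[mid]]
        fit <- fit_clogit(d, c(cols[mm], adj_terms), quiet = TRUE)
        multi_fits[[mid]] <- fit
        for (m in mm) {
          others <- setdiff(mm, m)
          r_other <- multiple_correlation(d, cols[[m]], cols[others], ctl)
          b <- fit$beta[[cols[[m]]]]
          se_b <- fit$se[[cols[[m]]]]
          sc <- bivariable_opera(b, r_other, se_b)
          multi[[length(multi) + 1L]] <- tibble::tibble(
            outcome = o, scale = s, model_id = as.integer(mid),
            model = paste(mm, collapse = "+"), measure = m,
            log_or = b, se = se_b, r_other = r_other,
            multiplier = sqrt(1 - r_other^2),
            log_opera = sc$log_opera, opera = sc$opera,
            conf.low = sc$conf.low, conf.high = sc$conf.high,
            p.value = 2 * pnorm(-abs(b / se_b)),
            loglik = fit$loglik, converged = fit$converged
          )
        }
        # LRT of each nested reduction: the univariable fits inside pairs,
        # and the pairwise fits inside the trivariable model
        reductions <- if (length(mm) == 2L) mm else c("1", "2", "3")
        for (red in reductions) {
          red_fit <- if (length(mm) == 2L) uni_fits[[red]] else multi_fits[[red]]
          red_label <- if (length(mm) == 2L) red else paste(grid_models()[[red]], collapse = "+")
          lt <- likelihood_ratio_test(fit, red_fit)
          lrt[[length(lrt) + 1L]] <- tibble::tibble(
            outcome = o, scale = s,
            full_model = paste(mm, collapse = "+"), reduced_model = red_label,
            statistic = lt$statistic, df = lt$df, p.value = lt$p.value,
            loglik_full = lt$loglik_full, loglik_reduced = lt$loglik_reduced
          )
        }
      }

      # equal-parameter BIC comparisons between measures within this scale
      pairs <- utils::combn(grid_measures(), 2L, simplify = FALSE)
      for (pr in pairs) {
        cmp <- delta_bic(uni_fits[[pr[1]]]$loglik, uni_fits[[pr[2]]]$loglik,
                         convention = config$bic_convention)
        bic[[length(bic) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(outcome = o, comparison = "measure",
                         model_a = paste(pr[1], s), model_b = paste(pr[2], s)),
          cmp
        )
      }
    }

    # same measure across scales (dense area vs percent), equal parameters
    if (all(c("dense_area", "percent") %in% config$scales)) {
      uni_tbl <- dplyr::bind_rows(uni)
      for (m in grid_measures()) {
        ll <- function(s) {
          uni_tbl$loglik[uni_tbl$outcome == o & uni_tbl$scale == s &
                           uni_tbl$measure == m]
        }
        cmp <- delta_bic(ll("percent"), ll("dense_area"),
                         convention = config$bic_convention)
        bic[[length(bic) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(outcome = o, comparison = "scale",
                         model_a = paste(m, "percent"),
                         model_b = paste(m, "dense_area")),
          cmp
        )
      }
    }
  }

  structure(
    list(
      univariable = dplyr::bind_rows(uni),
      multivariable = dplyr::bind_rows(multi),
      lrt = dplyr::bind_rows(lrt),
      bic = dplyr::bind_rows(bic),
      config = config
    ),
    class = "opera_grid"
  )
}

# correlation of `col` with the best linear combination of `others` among
# controls (plain correlation when one other, multiple correlation otherwise)
multiple_correlation <- function(d, col, others, ctl) {
  y <- d[[col]][ctl]
  if (length(others) == 1L) return(cor(y, d[[others]][ctl]))
  X <- as.matrix(d[ctl, others])
  sqrt(summary(lm(y ~ X))$r.squared)
}

#' @export
print.opera_grid <- function(x, ...) {
  cat(sprintf(
    "<opera_grid> %d univariable fit(s), %d multivariable term(s), %d LRT(s), %d BIC comparison(s)\n",
    nrow(x$univariable), nrow(x$multivariable), nrow(x$lrt), nrow(x$bic)
  ))
  print(dplyr::select(
    x$univariable, "outcome", "scale", "measure", "opera",
    "conf.low", "conf.high", "auc", "loglik"
  ))
  invisible(x)
}

#' Test whether the two outcomes need different density models
#'
#' Compares one shared conditional-logistic model for both modes of
#' detection against separate per-mode models of the same terms:
#' `LL(separate) = LL(interval) + LL(screen)` and
#' `2 * (LL(separate) - LL(combined))` is referred to chi-squared with
#' `(number of modes - 1) * (number of terms)` degrees of freedom.
#'
#' @param cohort A standardized cohort containing both outcome modes.
#' @param terms Model terms (standardized measure columns, covariates).
#' @param set,case Matched-set id and case-flag column names.
#' @return A one-row tibble: `statistic`, `df`, `p.value`,
#'   `loglik_combined`, `loglik_separate`.
#' @export
test_combined_vs_separate <- function(cohort, terms, set = "set_id",
                                      case = "case") {
  modes <- unique(cohort$mode)
  if (length(modes) < 2L) abort("Both outcome modes must be present.")
  fits <- purrr::map(modes, function(m) {
    d <- dplyr::filter(cohort, .data$mode == m)
    if (!nrow(d)) abort(paste0("Outcome has zero sets: ", m))
    fit_clogit(d, terms, set = set, case = case, quiet = TRUE)
  })
  combined <- fit_clogit(cohort, terms, set = set, case = case, quiet = TRUE)
  ll_sep <- sum(purrr::map_dbl(fits, "loglik"))
  stat <- max(0, 2 * (ll_sep - combined$loglik))
  df <- (length(modes) - 1L) * length(terms)
  tibble::tibble(
    statistic = stat, df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE),
    loglik_combined = combined$loglik, loglik_separate = ll_sep
  )
}

#' Render a model-grid results bundle to files
#'
#' Writes the four result tables as CSV, a human-readable `report.txt`, and
#' a `manifest.txt` recording the configuration and package version. Output
#' is deterministic given the bundle.
#'
#' @param grid An [run_model_grid()] result.
#' @param path Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(grid, path) {
  stopifnot(inherits(grid, "opera_grid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(paste0("Cannot create output directory: ", path))
  files <- c(
    univariable = file.path(path, "univariable.csv"),
    multivariable = file.path(path, "multivariable.csv"),
    lrt = file.path(path, "lrt.csv"),
    bic = file.path(path, "bic.csv")
  )
  for (nm in names(files)) {
    readr::write_csv(grid[[nm]], files[[nm]], progress = FALSE)
  }

  rpt <- file.path(path, "report.txt")
  lines <- c("Density model grid", "==================", "")
  u <- grid$univariable
  for (i in seq_len(nrow(u))) {
    lines <- c(lines, sprintf(
      "%-8s %-10s %-7s OPERA %.2f (%.2f-%.2f)  AUC %.2f (%.2f-%.2f)  LL %.2f",
      u$outcome[i], u$scale[i], u$measure[i], u$opera[i], u$conf.low[i],
      u$conf.high[i], u$auc[i], u$auc_low[i], u$auc_high[i], u$loglik[i]
    ))
  }
  lines <- c(lines, "", "Multivariable OPERAs (rescaled per residual SD)", "")
  m <- grid$multivariable
  for (i in seq_len(nrow(m))) {
    lines <- c(lines, sprintf(
      "%-8s %-10s model %d %-22s %-7s OPERA %.2f (%.2f-%.2f)  P %.3g",
      m$outcome[i], m$scale[i], m$model_id[i], m$model[i], m$measure[i],
      m$opera[i], m$conf.low[i], m$conf.high[i], m$p.value[i]
    ))
  }
  lines <- c(lines, "", "BIC comparisons", "")
  b <- grid$bic
  for (i in seq_len(nrow(b))) {
    lines <- c(lines, sprintf(
      "%-8s %-24s vs %-24s dBIC %8.2f  odds %10.3g  %s",
      b$outcome[i], b$model_a[i], b$model_b[i], b$delta_bic[i],
      b$posterior_odds[i], b$strength[i]
    ))
  }
  writeLines(lines, rpt)

  manifest <- file.path(path, "manifest.txt")
  cfg <- grid$config
  writeLines(c(
    sprintf("package: operamd %s", as.character(utils::packageVersion("operamd"))),
    sprintf("outcomes: %s", paste(cfg$outcomes, collapse = ", ")),
    sprintf("scales: %s", paste(cfg$scales, collapse = ", ")),
    sprintf("bic_convention: %s", cfg$bic_convention),
    sprintf("include_bmi: %s", cfg$include_bmi),
    sprintf("interaction_screen: %s", cfg$interaction_screen),
    sprintf("seed: %s", cfg$seed %||% "none")
  ), manifest)

  invisible(c(files, report = rpt, manifest = manifest))
}
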