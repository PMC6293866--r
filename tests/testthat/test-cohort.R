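small_params <- function(...) {
  sim_params(n_sets_interval = 40L, n_sets_screen = 40L, seed = 9, ...)
}

test_that("cohort structure: counts, one case per set, shared matching variable", {
  cohort <- generate_matched_sets(small_params(), quiet = TRUE)
  expect_equal(nrow(cohort), 80L * 4L)
  counts <- tapply(cohort$case, cohort$set_id, sum)
  expect_true(all(counts == 1L))
  by_set <- tapply(cohort$birth_year, cohort$set_id,
                   function(v) length(unique(v)))
  expect_true(all(by_set == 1L))
  expect_equal(sort(unique(cohort$mode)), c("interval", "screen"))
})

test_that("generated density values respect range and nesting invariants", {
  cohort <- generate_matched_sets(small_params(), quiet = TRUE)
  for (m in density_measures()) expect_true(all(cohort[[m]] > 0))
  pct <- c("cumulus_pct", "alto_pct", "cirro_pct")
  expect_true(all(as.matrix(cohort[pct]) <= 100))
  expect_true(all(cohort$cumulus_da >= cohort$alto_da))
  expect_true(all(cohort$alto_da >= cohort$cirro_da))
  expect_true(all(cohort$cumulus_pct >= cohort$alto_pct))
  expect_true(all(cohort$alto_pct >= cohort$cirro_pct))
})

test_that("raw marginals track the configured means and SDs among controls", {
  p <- sim_params(n_sets_interval = 600L, n_sets_screen = 0L, seed = 4)
  cohort <- generate_matched_sets(p, quiet = TRUE)
  ctl <- cohort$case == 0
  expect_equal(mean(cohort$cumulus_da[ctl]), 19, tolerance = 0.1 * 19)
  expect_equal(sd(cohort$cumulus_da[ctl]), 11, tolerance = 0.15 * 11)
  expect_equal(mean(cohort$bmi[ctl]), 26.5, tolerance = 0.5)
  expect_equal(mean(cohort$age[ctl]), 56.2, tolerance = 0.8)
})

test_that("null effects give a uniform case position within sets", {
  p <- sim_params(
    n_sets_interval = 2000L, n_sets_screen = 0L,
    beta_interval = numeric(), seed = 13
  )
  cohort <- generate_matched_sets(p, quiet = TRUE)
  pos <- tapply(seq_len(nrow(cohort)), cohort$set_id, function(i) {
    which(cohort$case[i] == 1L)
  })
  tab <- table(factor(pos, levels = 1:4))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
})

test_that("two-member set follows the closed-form logistic probability", {
  # P(member with x = 1 is the case) = e^beta / (e^beta + 1) when the other
  # member has x = 0; checked by Monte Carlo against the mechanism
  beta <- 0.8
  p <- sim_params(
    n_sets_interval = 0L, n_sets_screen = 0L, controls_per_case = 1L
  )
  p$n_sets_interval <- 100000L
  p$beta_interval <- c(cumulus_pct = beta)
  cohort <- generate_matched_sets(p, seed = 17, keep_latent = TRUE, quiet = TRUE)
  # emulate the x = (1, 0) contrast: within each pair the case probability is
  # plogis(beta * (z1 - z2)); average the indicator against the closed form
  z <- matrix(cohort$.z_cumulus_pct, ncol = 2, byrow = TRUE)
  case1 <- matrix(cohort$case, ncol = 2, byrow = TRUE)[, 1] == 1
  pexp <- plogis(beta * (z[, 1] - z[, 2]))
  expect_equal(mean(case1 - pexp), 0, tolerance = 0.005)
  # calibration: regressing the indicator on the closed-form probability
  # gives slope 1
  expect_equal(unname(coef(lm(case1 ~ pexp))[2]), 1, tolerance = 0.05)
})

test_that("conditional-likelihood consistency: fitted beta recovers the truth", {
  for (beta in c(0, 0.3, log(2.33))) {
    rec <- simulate_opera_recovery(30, 120, beta, seed = 100 + round(100 * beta))
    se_mean <- sd(rec$beta_hat) / sqrt(nrow(rec))
    expect_lt(abs(mean(rec$beta_hat) - beta), 2 * se_mean + 0.02)
  }
})

test_that("repeat measurements hit the requested repeatability limits", {
  exact <- generate_repeat_measurements(50, icc_true = 1, seed = 2)
  expect_equal(icc(exact, pair_id, value)$icc, 1)
  set.seed(3)
  noise <- purrr::map_dbl(1:40, function(i) {
    icc(generate_repeat_measurements(200, icc_true = 0), pair_id, value)$icc
  })
  expect_lt(abs(mean(noise)), 0.03)
})

test_that("cohort CSV round-trips losslessly and is byte-stable under a seed", {
  cohort <- generate_matched_sets(small_params(), quiet = TRUE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, f1)
  back <- read_cohort(f1)
  expected <- cohort[names(back)]
  attr(expected, "params") <- NULL
  attr(expected, "n_nesting_clamped") <- NULL
  attr(expected, "n_backtransform_clamped") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(expected))
  write_cohort(generate_matched_sets(small_params(), quiet = TRUE), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed cohort rows are reported with line numbers", {
  cohort <- generate_matched_sets(small_params(), quiet = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  lines <- readLines(f)
  lines[3] <- sub(",interval,", ",interval,not_a_number_", lines[3], fixed = TRUE)
  writeLines(lines, f)
  expect_error(suppressWarnings(read_cohort(f)), "line")
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(controls_per_case = 0), "at least 1")
  expect_error(sim_params(icc_true = 1.2), "0, 1")
  expect_error(sim_params(raw_sd = setNames(rep(-1, 6), density_measures())),
               "positive")
  bad <- default_density_corr()
  bad[1, 2] <- 0.5 # asymmetric
  expect_error(sim_params(corr_matrix = bad), "symmetric")
})
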