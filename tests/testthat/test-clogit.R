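test_that("null conditional log-likelihood is -sum(log(set size))", {
  d <- make_sets(168, 3, beta = 0, seed = 71)
  expect_equal(conditional_loglik(d, 0, "x1"), -168 * log(4))
  fit <- fit_clogit(d, "x1")
  expect_equal(fit$loglik_null, -168 * log(4))
})

test_that("single-set likelihood matches direct enumeration", {
  d <- tibble::tibble(set_id = 1, case = c(1, 0, 0, 0), x = c(1, 0, 0, 0))
  expect_equal(conditional_loglik(d, log(3), "x"), log(0.5))
})

test_that("likelihood and fit are invariant to set-constant covariate shifts", {
  d <- make_sets(50, 3, beta = 0.5, seed = 73)
  shift <- rnorm(50)[d$set_id]
  d2 <- dplyr::mutate(d, x1 = x1 + shift)
  expect_equal(conditional_loglik(d, 0.4, "x1"),
               conditional_loglik(d2, 0.4, "x1"))
  f1 <- fit_clogit(d, "x1")
  f2 <- fit_clogit(d2, "x1")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("stabilized likelihood equals the naive enumeration oracle", {
  d <- make_sets(20, 3, beta = c(0.5, -0.3), seed = 79)
  for (b in list(c(0, 0), c(1, -1), c(-2, 0.5))) {
    expect_equal(conditional_loglik(d, b, c("x1", "x2")),
                 naive_cloglik(d, b, c("x1", "x2")))
  }
})

test_that("Newton estimate matches a fine grid search on hand-built sets", {
  d <- tibble::tibble(
    set_id = rep(1:5, each = 3),
    case = rep(c(1, 0, 0), 5),
    x = c(0.8, -0.2, 0.1, 1.4, 0.5, -0.3, -0.1, 0.2, -0.9,
          0.6, 0.6, -0.5, 1.0, -1.2, 0.3)
  )
  fit <- fit_clogit(d, "x")
  grid <- seq(-2, 5, by = 1e-4)
  ll <- vapply(grid, function(b) naive_cloglik(d, b, "x"), numeric(1))
  oracle <- grid[which.max(ll)]
  expect_equal(round(fit$beta[["x"]], 4), round(oracle, 4))
})

test_that("estimates, SEs and log-likelihood agree with survival::clogit", {
  skip_if_not_installed("survival")
  d <- make_sets(120, 3, beta = c(0.6, -0.4), seed = 83)
  fit <- fit_clogit(d, c("x1", "x2"))
  sf <- survival::coxph(
    survival::Surv(rep(1, nrow(d)), case) ~ x1 + x2 + survival::strata(set_id),
    data = d, method = "exact"
  )
  expect_equal(unname(fit$beta), unname(coef(sf)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sf)))), tolerance = 1e-6)
  expect_equal(fit$loglik, sf$loglik[2], tolerance = 1e-8)
})

test_that("sets violating the one-case rule are named", {
  d <- make_sets(5, 2, beta = 0, seed = 87)
  d$case[d$set_id == 3] <- 0
  expect_error(fit_clogit(d, "x1"), "exactly one case")
})

test_that("missing covariates drop subjects, and whole sets when the case is lost", {
  d <- make_sets(40, 3, beta = 0.4, seed = 89)
  d$x1[2] <- NA # a control
  d$x1[d$set_id == 7 & d$case == 1] <- NA # a case
  expect_message(fit <- fit_clogit(d, "x1"), "dropped 5 subject")
  expect_equal(fit$n_sets, 39L)
  expect_equal(fit$n_dropped_sets, 1L)
})

test_that("data without within-set variation cannot be fitted", {
  d <- make_sets(10, 2, beta = 0, seed = 91)
  d$flat <- rnorm(10)[d$set_id]
  expect_error(fit_clogit(d, "flat"), "informative")
})

test_that("Wald intervals attain nominal coverage under the null", {
  covered <- vapply(1:500, function(i) {
    d <- make_sets(500, 3, beta = 0, seed = 9000 + i)
    fit <- fit_clogit(d, "x1")
    abs(fit$beta[[1]]) <= Z975_test * fit$se[[1]]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("likelihood-ratio test contracts hold", {
  d <- make_sets(100, 3, beta = c(0.5, 0), seed = 93)
  full <- fit_clogit(d, c("x1", "x2"))
  reduced <- fit_clogit(d, "x1")
  lt <- likelihood_ratio_test(full, reduced)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$df, 1L)
  # identical models: statistic 0, p = 1
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # chi-squared reference: statistic 3.84 on 1 df sits at p ~ 0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 0.001)
  # non-nested specs fail
  other <- fit_clogit(d, "x2")
  expect_error(likelihood_ratio_test(other, reduced), "not nested")
})

test_that("null LRT p-values are uniform with nominal type-I error", {
  pvals <- vapply(1:1000, function(i) {
    d <- make_sets(60, 3, beta = c(0.3, 0), seed = 20000 + i)
    full <- fit_clogit(d, c("x1", "x2"))
    reduced <- fit_clogit(d, "x1")
    likelihood_ratio_test(full, reduced)$p.value
  }, numeric(1))
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.02)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("unconditional logistic regression matches closed forms", {
  # balanced outcome with a null covariate
  set.seed(95)
  d0 <- tibble::tibble(y = rep(0:1, each = 100), x = rnorm(200))
  f0 <- fit_unconditional_logit(d0, "x", "y")
  expect_lt(abs(f0$beta[[1]]), 2 * f0$se[[1]] + 0.05)
  # 2x2 table (a, b, c, d) = (44, 124, 75, 423): OR = 44*423 / (124*75)
  tab <- tibble::tibble(
    exposed = c(rep(1, 44 + 75), rep(0, 124 + 423)),
    y = c(rep(1, 44), rep(0, 75), rep(1, 124), rep(0, 423))
  )
  ft <- fit_unconditional_logit(tab, "exposed", "y")
  expect_equal(exp(ft$beta[[1]]), (44 * 423) / (124 * 75), tolerance = 1e-6)
  expect_equal(round(exp(ft$beta[[1]]), 2), 2.00)
})

test_that("unconditional fit matches a dense 2-d grid search on 20 records", {
  set.seed(97)
  d <- tibble::tibble(x = rnorm(20), y = rbinom(20, 1, 0.5))
  fit <- fit_unconditional_logit(d, "x", "y")
  a_grid <- seq(-2, 2, by = 0.01)
  b_grid <- seq(-2, 2, by = 0.01)
  ll <- function(a, b) {
    eta <- a + b * d$x
    sum(d$y * eta - log(1 + exp(eta)))
  }
  vals <- outer(a_grid, b_grid, Vectorize(ll))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  expect_lt(abs(fit$beta[[1]] - b_grid[best[2]]), 0.011)
  expect_lt(abs(fit$intercept - a_grid[best[1]]), 0.011)
})
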