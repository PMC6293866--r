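test_that("OPERA from a fit exponentiates the coefficient with Wald limits", {
  d <- make_sets(200, 3, beta = 0.6, seed = 101)
  fit <- fit_clogit(d, "x1")
  op <- opera_from_fit(fit)
  expect_equal(op$opera, exp(fit$beta[[1]]))
  expect_equal(op$conf.low, exp(fit$beta[[1]] - Z975_test * fit$se[[1]]))
  expect_equal(op$iqrr, op$opera^2.5)
  # a zero coefficient maps to OPERA 1 and IQRR 1
  fit0 <- fit
  fit0$beta[1] <- 0
  op0 <- opera_from_fit(fit0)
  expect_equal(op0$opera, 1)
  expect_equal(op0$iqrr, 1)
  # printed-precision anchors of the log / OR correspondence
  expect_equal(round(exp(0.61), 2), 1.84)
  expect_equal(round(exp(0.28), 2), 1.32)
})

test_that("non-converged fits are refused", {
  d <- make_sets(20, 3, beta = 0.5, seed = 103)
  fit <- fit_clogit(d, "x1")
  fit$converged <- FALSE
  expect_error(opera_from_fit(fit), "non-converged")
})

test_that("bivariable rescaling follows sqrt(1 - r^2)", {
  # r = 0 leaves the joint estimate unchanged
  expect_equal(bivariable_opera(0.7, 0)$opera, exp(0.7))
  # printed correlation 0.82: multiplier sqrt(1 - 0.6724), OPERA e^0.5724
  sc <- bivariable_opera(1, 0.82)
  expect_equal(sc$log_opera, sqrt(1 - 0.82^2), tolerance = 1e-6)
  expect_equal(sc$opera, exp(sqrt(1 - 0.82^2)), tolerance = 1e-6)
  expect_equal(round(sc$opera, 2), 1.77)
  # CI endpoints scale identically
  sc2 <- bivariable_opera(1, 0.82, se = 0.2)
  expect_equal(sc2$conf.low, exp((1 - Z975_test * 0.2) * sqrt(1 - 0.82^2)))
  expect_error(bivariable_opera(1, 1), "indistinguishable")
})

test_that("jointly fitting a null correlated measure collapses its OPERA only", {
  set.seed(107)
  n_sets <- 400
  msize <- 4
  n <- n_sets * msize
  z <- generate_latent_traits(n, matrix(c(1, 0.82, 0.82, 1), 2))
  eta <- 0.85 * z[, 1] # only the first measure is causal
  case <- integer(n)
  for (s in seq_len(n_sets)) {
    idx <- ((s - 1) * msize + 1):(s * msize)
    case[idx[sample.int(msize, 1, prob = exp(eta[idx] - max(eta[idx])))]] <- 1L
  }
  d <- tibble::tibble(set_id = rep(seq_len(n_sets), each = msize), case = case,
                      m1 = z[, 1], m2 = z[, 2])
  fit <- fit_clogit(d, c("m1", "m2"))
  r <- cor(z[, 1], z[, 2])
  sc <- bivariable_opera(unname(fit$beta), r, unname(fit$se))
  # causal measure stays elevated, null measure's scaled OPERA near 1
  expect_gt(sc$opera[1], 1.3)
  expect_lt(abs(log(sc$opera[2])), 0.25)
})

test_that("inter-quartile risk ratio arithmetic and properties", {
  expect_equal(iqrr(1), 1)
  expect_equal(round(iqrr(2.33)), 8)
  expect_equal(iqrr(1.35), 1.35^2.5)
  expect_equal(round(iqrr(1.35), 2), 2.12)
  # strictly increasing; reciprocal symmetry
  x <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(iqrr(x)) > 0))
  expect_equal(iqrr(1 / x), 1 / iqrr(x))
  expect_error(iqrr(-1), "positive")
})

test_that("BIC differences, posterior odds and strength bands", {
  # equal parameters: delta_bic = -2 * delta_ll; -6 is ~400:1, -14 ~10^6:1
  cmp6 <- delta_bic(-100, -103)
  expect_equal(cmp6$delta_bic, -6)
  expect_equal(round(cmp6$posterior_odds / 100) * 100, 400)
  cmp14 <- delta_bic(-100, -107)
  expect_equal(signif(cmp14$posterior_odds, 1), 1e6)
  expect_equal(cmp14$strength, "very strong")
  # zero difference: odds 1, no evidence
  cmp0 <- delta_bic(-50, -50)
  expect_equal(cmp0$posterior_odds, 1)
  expect_equal(cmp0$strength, "none")
  # reciprocal symmetry of the posterior odds
  expect_equal(delta_bic(-100, -102)$posterior_odds *
                 delta_bic(-102, -100)$posterior_odds, 1)
  # unequal parameter counts need n, and add (k_a - k_b) log n
  expect_error(delta_bic(-100, -103, k_a = 2, k_b = 1), "`n`")
  cmpk <- delta_bic(-100, -103, k_a = 2, k_b = 1, n = 100)
  expect_equal(cmpk$delta_bic, -6 + log(100))
  # halved convention
  expect_equal(delta_bic(-100, -103, convention = "halved")$posterior_odds,
               exp(3))
  # band edges
  expect_equal(delta_bic(-100, -101.5)$strength, "positive")
  expect_equal(delta_bic(-100, -103.5)$strength, "strong")
})

test_that("AUC behaves at its closed-form anchors", {
  set.seed(109)
  # identical distributions: AUC near 0.5
  v <- rnorm(2000)
  flag <- rep(0:1, 1000)
  expect_equal(auc_adjusted(v, flag)$auc, 0.5, tolerance = 0.03)
  # perfect separation (pROC warns that the degenerate CI is 1-1)
  sep <- suppressWarnings(
    auc_adjusted(c(rnorm(100, 10), rnorm(100, -10)), rep(1:0, each = 100))
  )
  expect_equal(sep$auc, 1)
  # binormal shift delta: AUC = pnorm(delta / sqrt(2)); delta = log 2.33
  delta <- log(2.33)
  vals <- c(rnorm(20000), rnorm(20000, delta))
  flags <- rep(0:1, each = 20000)
  expect_equal(auc_adjusted(vals, flags)$auc, pnorm(delta / sqrt(2)),
               tolerance = 0.01)
  expect_equal(pnorm(delta / sqrt(2)), 0.725, tolerance = 0.001)
  expect_error(auc_adjusted(rnorm(5), rep(1, 5)), "cases and controls")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(113)
  vals <- rnorm(600, mean = rep(c(0, 0.8), each = 300))
  flags <- rep(0:1, each = 300)
  a0 <- auc_adjusted(vals, flags)$auc
  expect_equal(auc_adjusted(exp(vals), flags)$auc, a0)
  expect_equal(auc_adjusted(vals^3, flags)$auc, a0)
  expect_equal(auc_adjusted(rank(vals), flags)$auc, a0)
})

test_that("quartile assignment of a hand-made 8-control set splits 2/2/2/2", {
  d <- tibble::tibble(
    set_id = rep(1:2, each = 5),
    case = rep(c(1, 0, 0, 0, 0), 2),
    m = c(10, 1, 2, 3, 4, 20, 5, 6, 7, 8),
    age = 0, bmi = 0, livebirths = 0
  )
  q <- quartile_ors(d, "m")
  tab <- table(attr(q, "quartile")[d$case == 0])
  expect_equal(as.integer(tab), c(2L, 2L, 2L, 2L))
})

test_that("quartile odds ratios are flat under the null and ordered under effect", {
  set.seed(115)
  d0 <- make_sets(600, 3, beta = 0, seed = 117)
  d0$age <- rnorm(nrow(d0), 56, 7)
  d0$bmi <- rnorm(nrow(d0), 26, 5)
  d0$livebirths <- rpois(nrow(d0), 2.7)
  q0 <- quartile_ors(d0, "x1")
  expect_lt(max(abs(log(q0$or[-1]))), 0.35)
  d1 <- make_sets(600, 3, beta = 0.85, seed = 119)
  d1$age <- rnorm(nrow(d1), 56, 7)
  d1$bmi <- rnorm(nrow(d1), 26, 5)
  d1$livebirths <- rpois(nrow(d1), 2.7)
  q1 <- quartile_ors(d1, "x1")
  expect_true(all(diff(q1$or) > 0))
  expect_gt(q1$or[4], 2)
  # degenerate cut-points are named
  dd <- tibble::tibble(
    set_id = rep(1:4, each = 4),
    case = rep(c(1, 0, 0, 0), 4),
    m = rep(c(1, 2), 8), # two-valued measure collapses the quartiles
    age = 0, bmi = 0, livebirths = 0
  )
  expect_error(quartile_ors(dd, "m"), "Degenerate")
})

test_that("ICC estimator covers its limits and the repeatability design", {
  # exact duplicates
  dup <- tibble::tibble(pair_id = rep(1:30, each = 2),
                        replicate = rep(1:2, 30),
                        value = rep(rnorm(30), each = 2))
  expect_equal(icc(dup, pair_id, value)$icc, 1)
  # independent pair members at 1000 pairs
  set.seed(121)
  ind <- tibble::tibble(pair_id = rep(1:1000, each = 2),
                        replicate = rep(1:2, 1000),
                        value = rnorm(2000))
  expect_lt(abs(icc(ind, pair_id, value)$icc), 0.05)
  # all-singleton groups are rejected
  single <- tibble::tibble(pair_id = 1:10, value = rnorm(10))
  expect_error(icc(single, pair_id, value), "two or more")
  # repeatability design: mean estimate over replicates near the truth
  ests <- vapply(1:100, function(i) {
    icc(generate_repeat_measurements(180, 0.95, seed = 3000 + i),
        pair_id, value)$icc
  }, numeric(1))
  expect_equal(mean(ests), 0.95, tolerance = 0.01)
})
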