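# shared test fixtures and independent oracles, built in code

Z975_test <- 1.959964

# quick matched-set generator with explicit covariate columns and exact
# softmax case assignment -- an independent re-implementation of the
# conditional-logistic mechanism used to cross-validate the package one
make_sets <- function(n_sets, m_controls, beta, seed,
                      covariates = length(beta)) {
  set.seed(seed)
  msize <- m_controls + 1L
  n <- n_sets * msize
  X <- matrix(rnorm(n * covariates), nrow = n)
  eta <- drop(X %*% beta)
  case <- integer(n)
  for (s in seq_len(n_sets)) {
    idx <- ((s - 1L) * msize + 1L):(s * msize)
    p <- exp(eta[idx] - max(eta[idx]))
    case[idx[sample.int(msize, 1L, prob = p)]] <- 1L
  }
  d <- tibble::tibble(
    set_id = rep(seq_len(n_sets), each = msize),
    case = case
  )
  for (j in seq_len(covariates)) d[[paste0("x", j)]] <- X[, j]
  d
}

# independent conditional log-likelihood: direct per-set enumeration,
# no log-sum-exp, no shared code with the package implementation
naive_cloglik <- function(data, beta, terms) {
  X <- as.matrix(data[terms])
  ll <- 0
  for (s in unique(data$set_id)) {
    rows <- which(data$set_id == s)
    eta <- as.numeric(X[rows, , drop = FALSE] %*% beta)
    ll <- ll + eta[data$case[rows] == 1] - log(sum(exp(eta)))
  }
  ll
}

# independent Box-Cox profile log-likelihood for the grid oracle
naive_boxcox_profile <- function(y, lambda) {
  z <- if (lambda == 0) log(y) else (y^lambda - 1) / lambda
  n <- length(y)
  -n / 2 * log(sum((z - mean(z))^2) / n) + (lambda - 1) * sum(log(y))
}

# small two-region phantom: 50x50 breast at 500 with a 10x10 patch at 3000
breast_phantom <- function(spacing = 0.1) {
  synth_mammogram(
    width = 60, height = 60,
    shapes = data.frame(
      shape = c("rect", "rect"),
      x0 = c(6L, 20L), y0 = c(6L, 20L),
      w = c(50L, 10L), h = c(50L, 10L),
      r = NA, intensity = c(500L, 3000L)
    ),
    allow_overlap = TRUE, pixel_spacing = spacing
  )
}
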