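#' Draw correlated standard-normal latent traits
#'
#' Samples `n` rows from a multivariate normal with zero mean, unit variances
#' and the given correlation matrix, via a symmetric eigen square root.
#' Singular (positive semi-definite) matrices are allowed, so perfectly
#' correlated traits can be generated; matrices with a negative eigenvalue are
#' rejected.
#'
#' @param n Number of rows to draw.
#' @param corr_matrix Correlation matrix (symmetric, unit diagonal, PSD).
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return An `n` x `ncol(corr_matrix)` matrix; column means approach 0 and
#'   column SDs approach 1 as `n` grows, with empirical correlations
#'   converging to `corr_matrix`.
#' @examples
#' z <- generate_latent_traits(500, default_density_corr(), seed = 1)
#' round(cor(z)[1, 3], 2) # near 0.86
#' @export
generate_latent_traits <- function(n, corr_matrix, seed = NULL) {
  check_corr_matrix(corr_matrix)
  eg <- eigen(corr_matrix, symmetric = TRUE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  k <- ncol(corr_matrix)
  z <- with_seed(seed, matrix(rnorm(n * k), nrow = n, ncol = k)) %*% root
  colnames(z) <- colnames(corr_matrix)
  z
}

#' Map standard-normal traits to raw-scale density values
#'
#' Inverts the Box-Cox transform so that a latent `z ~ N(0, 1)` yields a
#' positive raw-scale value whose marginal mean and SD match the targets:
#' exactly for `lambda = 1` (affine) and `lambda = 0` (log-normal moment
#' matching), and to first order (delta method) otherwise. Applying the
#' forward Box-Cox transform with the same `lambda` recovers `z` up to an
#' affine map.
#'
#' @param z Numeric vector of standard-normal latent values.
#' @param lambda Box-Cox shape of the raw measure.
#' @param raw_mean,raw_sd Target raw-scale mean and SD (`raw_mean > 0`,
#'   `raw_sd > 0`).
#' @param floor Positive floor at which raw values are clamped when the
#'   Box-Cox base `lambda * t + 1` would be non-positive; clamp counts are
#'   reported via a message and the `"n_clamped"` attribute.
#' @param quiet Suppress the clamp-count message (the attribute is always
#'   set).
#' @return Numeric vector of positive raw-scale values with attribute
#'   `n_clamped`.
#' @examples
#' raw <- backtransform_to_raw(rnorm(1000), lambda = 0, raw_mean = 19, raw_sd = 11)
#' c(mean(raw), sd(raw)) # close to 19 and 11
#' @export
backtransform_to_raw <- function(z, lambda, raw_mean, raw_sd, floor = 1e-3,
                                 quiet = FALSE) {
  stopifnot(raw_mean > 0, raw_sd > 0, floor > 0)
  if (abs(lambda) < 1e-12) {
    s2 <- log(1 + (raw_sd / raw_mean)^2) # exact log-normal moment match
    t <- (log(raw_mean) - s2 / 2) + sqrt(s2) * z
    raw <- exp(t)
    n_clamped <- 0L
  } else {
    mu_t <- (raw_mean^lambda - 1) / lambda
    sd_t <- raw_sd * raw_mean^(lambda - 1) # delta-method scale match
    t <- mu_t + sd_t * z
    base <- lambda * t + 1
    bad <- base <= 0
    n_clamped <- sum(bad)
    raw <- rep(floor, length(z))
    raw[!bad] <- base[!bad]^(1 / lambda)
    raw[raw < floor] <- floor
  }
  if (n_clamped > 0L && !quiet) {
    inform(sprintf(
      "backtransform_to_raw: clamped %d of %d values at floor %.3g.",
      n_clamped, length(z), floor
    ))
  }
  attr(raw, "n_clamped") <- n_clamped
  raw
}
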