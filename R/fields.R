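#' Simulate a stationary Gaussian random field
#'
#' Draws one realisation of a zero-mean stationary Gaussian process on
#' arbitrary planar coordinates using a random-Fourier-feature expansion of
#' the squared-exponential covariance
#' \eqn{C(d) = \sigma^2 \exp\{-d^2 / (2\,\mathrm{range}^2)\}}.
#' The expansion is exact in the limit of many features; 256 features give
#' fields indistinguishable from a direct Cholesky draw at the smoothness
#' used here, at O(n) cost instead of O(n^3).
#'
#' Uses the current RNG state; callers are responsible for seeding.
#'
#' @param coords two-column matrix or data.frame of planar coordinates (km).
#' @param range_km correlation length-scale in km.
#' @param sd marginal standard deviation of the field.
#' @param n_features number of random Fourier features.
#' @return numeric vector, one value per row of `coords`.
#' @export
sim_grf <- function(coords, range_km, sd = 1, n_features = 256L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, range_km > 0, sd >= 0)
  k <- as.integer(n_features)
  w <- matrix(stats::rnorm(2L * k, sd = 1 / range_km), nrow = k)
  phase <- stats::runif(k, 0, 2 * pi)
  proj <- coords %*% t(w)                      # n x k
  drop(cos(sweep(proj, 2L, phase, "+")) %*% rep(sd * sqrt(2 / k), k))
}

# Space-time Gaussian field: a fixed set of spatial basis patterns (unit-sd
# GRFs) combined with AR(1) weights in time.  Marginal sd ~ `sd`, temporal
# lag-1 correlation ~ `ar1`, spatial length-scale `range_km`.
# Returns an n_locations x n_days matrix.
sim_daily_field <- function(coords, n_days, range_km, sd = 1, ar1 = 0.6,
                            n_basis = 24L) {
  n_basis <- as.integer(n_basis)
  basis <- vapply(
    seq_len(n_basis),
    function(i) sim_grf(coords, range_km = range_km, sd = 1),
    numeric(nrow(as.matrix(coords)))
  )
  innov_sd <- sd / sqrt(n_basis)
  coef <- matrix(0, n_basis, n_days)
  coef[, 1L] <- stats::rnorm(n_basis, sd = innov_sd)
  if (n_days > 1L) {
    scale <- sqrt(1 - ar1^2)
    for (t in 2L:n_days) {
      coef[, t] <- ar1 * coef[, t - 1L] +
        scale * stats::rnorm(n_basis, sd = innov_sd)
    }
  }
  basis %*% coef
}

# Gaussian-kernel proximity to the nearest urban centre, in (0, 1]:
# 1 at a centre, decaying with distance at scale `range_km`.
urban_kernel <- function(coords, centers, range_km) {
  coords <- as.matrix(coords)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  k <- matrix(0, nrow(coords), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d2 <- (coords[, 1L] - centers[j, 1L])^2 + (coords[, 2L] - centers[j, 2L])^2
    k[, j] <- exp(-d2 / (2 * range_km^2))
  }
  apply(k, 1L, max)
}

# Symmetric PSD square root via eigendecomposition (tolerates zero matrices,
# unlike chol()).
psd_sqrt <- function(m) {
  m <- as.matrix(m)
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1))) {
    stop("matrix is not positive semi-definite")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
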