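# Bipolar Watson distributions and Dirichlet-process mixtures of them:
# the synthetic fibre orientation distributions used for validation.

# log of the Kummer confluent hypergeometric M(1/2, 3/2, kappa) =
# integral_0^1 exp(kappa t^2) dt = sum_n kappa^n / (n! (2n+1)). All series
# terms are positive; the sum is taken in log space (log-sum-exp) so that
# arbitrarily large concentrations do not overflow.
kummer_watson_log <- function(kappa) {
  vapply(kappa, function(k) {
    if (k < 1e-12) return(log1p(k / 3))
    n <- 0:ceiling(k + 12 * sqrt(k + 9) + 30)
    lt <- n * log(k) - lgamma(n + 1) - log(2 * n + 1)
    m <- max(lt)
    m + log(sum(exp(lt - m)))
  }, numeric(1))
}

kummer_watson <- function(kappa) exp(kummer_watson_log(kappa))

#' Bipolar Watson density on the sphere
#'
#' `W(omega; mu, kappa) = exp(kappa <mu, omega>^2) / (4 pi M(1/2, 3/2, kappa))`,
#' an antipodally symmetric density that is uniform at `kappa = 0` and
#' concentrates around `+/- mu` as `kappa` grows.
#'
#' @param points N x 3 matrix of unit vectors (or vector of cosines via
#'   `cos_angle`).
#' @param axis Unit mean axis.
#' @param kappa Concentration, `kappa >= 0`.
#' @param cos_angle Optionally, evaluate directly at these values of
#'   `<mu, omega>` instead of `points`.
#' @return Density values (integrating to 1 over the sphere).
#' @export
watson_density <- function(points = NULL, axis = c(0, 0, 1), kappa,
                           cos_angle = NULL) {
  stopifnot(kappa >= 0)
  t <- if (is.null(cos_angle)) {
    axis <- axis / sqrt(sum(axis^2))
    as.vector(matrix(points, ncol = 3) %*% axis)
  } else cos_angle
  exp(kappa * t^2 - kummer_watson_log(kappa)) / (4 * pi)
}

#' Sample directions from a bipolar Watson distribution
#'
#' Rejection sampling from the uniform proposal: a uniform unit vector `x` is
#' accepted with probability `exp(kappa (<mu, x>^2 - 1))`. Reproducible given
#' the seed.
#'
#' @param axis Unit mean axis.
#' @param kappa Concentration, `kappa >= 0`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return `n` x 3 matrix of unit vectors.
#' @export
sample_watson <- function(axis = c(0, 0, 1), kappa, n, seed = NULL) {
  stopifnot(kappa >= 0, n >= 1)
  local_seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    X <- matrix(stats::rnorm(3 * m), m, 3)
    X <- X / sqrt(rowSums(X^2))
    t2 <- as.vector(X %*% axis)^2
    acc <- stats::runif(m) < exp(kappa * (t2 - 1))
    take <- which(acc)[seq_len(min(sum(acc), n - got))]
    if (length(take)) {
      out[got + seq_along(take), ] <- X[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

#' Watson-mixture orientation distribution
#'
#' A finite mixture of bipolar Watson components: the ground-truth fibre
#' orientation distributions of the simulator.
#'
#' @param weights Non-negative component weights; normalized to sum 1.
#' @param axes K x 3 matrix of unit axes (one row per component).
#' @param kappa Vector of concentrations, `>= 0`.
#' @return Object of class `"watson_mixture"`.
#' @export
watson_mixture <- function(weights, axes, kappa) {
  axes <- matrix(axes, ncol = 3)
  stopifnot(length(weights) == nrow(axes), length(kappa) == nrow(axes),
            all(weights >= 0), all(kappa >= 0), sum(weights) > 0)
  axes <- axes / sqrt(rowSums(axes^2))
  structure(list(weights = weights / sum(weights), axes = axes, kappa = kappa),
            class = "watson_mixture")
}

#' @export
print.watson_mixture <- function(x, ...) {
  cat("Watson mixture with", length(x$weights), "component(s)\n")
  print(data.frame(weight = round(x$weights, 4), kappa = round(x$kappa, 2),
                   axis = apply(round(x$axes, 3), 1, paste, collapse = ", ")),
        row.names = FALSE)
  invisible(x)
}

#' Evaluate a Watson-mixture density
#'
#' @param mixture A [watson_mixture()].
#' @param points N x 3 matrix of unit vectors.
#' @return Density values at the points.
#' @export
mixture_density <- function(mixture, points) {
  stopifnot(inherits(mixture, "watson_mixture"))
  points <- matrix(points, ncol = 3)
  dens <- numeric(nrow(points))
  for (j in seq_along(mixture$weights))
    dens <- dens + mixture$weights[j] *
      watson_density(points, mixture$axes[j, ], mixture$kappa[j])
  dens
}

#' Draw a random orientation distribution from a Dirichlet-process mixture
#'
#' Stick-breaking construction with bipolar Watson kernels: component weights
#' `w_k = beta_k prod_{j<k} (1 - beta_j)` with `beta_k ~ Beta(1, alpha)`,
#' truncated once the residual mass falls below `1e-3` and renormalized; axes
#' uniform on the sphere; concentrations uniform over `kappa_range`. The
#' draws span near-uniform distributions through sharp multi-fibre crossings.
#'
#' @param alpha Dirichlet-process concentration (default 2).
#' @param kappa_range Range of Watson concentrations (default `c(0, 128)`).
#' @param seed Optional integer seed.
#' @return A [watson_mixture()].
#' @export
sample_dpm_fod <- function(alpha = 2, kappa_range = c(0, 128), seed = NULL) {
  stopifnot(alpha > 0, length(kappa_range) == 2L, all(kappa_range >= 0))
  local_seed(seed)
  w <- numeric(0); rest <- 1
  while (rest >= 1e-3) {
    beta <- stats::rbeta(1, 1, alpha)
    w <- c(w, beta * rest)
    rest <- rest * (1 - beta)
  }
  k <- length(w)
  axes <- matrix(stats::rnorm(3 * k), k, 3)
  axes <- axes / sqrt(rowSums(axes^2))
  kap <- stats::runif(k, kappa_range[1], kappa_range[2])
  watson_mixture(w, axes, kap)
}

# Legendre (rotational) coefficients of the Watson density profile:
# w_l = 2 pi * integral_{-1}^{1} W(t) P_l(t) dt, so that
# W(<mu, omega>) = sum_l (2l+1)/(4 pi) w_l P_l(<mu, omega>), with w_0 = 1.
# Node count grows with kappa (the density sharpens near t = +/-1) and the
# coefficients are renormalized by the computed w_0 so that w_0 = 1 exactly.
watson_legendre_coef <- function(kappa, lmax, n_nodes = NULL) {
  if (is.null(n_nodes))
    n_nodes <- max(64L, as.integer(16 * ceiling(sqrt(kappa + 1))), lmax + 2L)
  gl <- gauss_legendre_cached(n_nodes, -1, 1)
  P <- legendre_poly(gl$x, lmax)
  dens <- watson_density(cos_angle = gl$x, kappa = kappa)
  coefs <- 2 * pi * as.vector(crossprod(P, gl$w * dens))
  coefs <- coefs / coefs[1]
  coefs[seq(2, lmax + 1, by = 2)] <- 0   # odd degrees vanish by symmetry
  coefs
}

#' Entropy of a bipolar Watson distribution (1-D quadrature oracle)
#'
#' Kullback-Leibler divergence of the Watson density from the uniform density
#' `1/(4 pi)`, computed by one-dimensional Gauss-Legendre quadrature using the
#' closed-form Kummer-series normalization. Used as an independent check of
#' the grid-based entropy.
#'
#' @param kappa Concentration.
#' @param n_nodes Quadrature nodes (default 128).
#' @return Entropy in nats, `>= 0`; 0 at `kappa = 0`.
#' @export
watson_entropy_oracle <- function(kappa, n_nodes = 128) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  p <- watson_density(cos_angle = gl$x, kappa = kappa)
  sum(gl$w * 2 * pi * p * log(4 * pi * p))
}
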