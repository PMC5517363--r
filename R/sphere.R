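# Spherical quadrature grids, Legendre polynomials, real spherical harmonics
# and near-uniform gradient direction sets.

# run expr with a temporary RNG state seeded by `seed`; restores the caller's
# stream on exit
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- if (has_old) bquote(assign(".Random.seed", .(old), globalenv()))
             else quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
                          rm(".Random.seed", envir = globalenv()))
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(NULL)
}

#' Product quadrature grid on the unit sphere
#'
#' Gauss-Legendre nodes in `cos(theta)` crossed with an equispaced azimuth:
#' integrates spherical polynomials exactly up to degree
#' `min(2 n_theta - 1, n_phi - 1)`. Weights sum to `4 pi`.
#'
#' @param n_theta Number of Gauss-Legendre polar nodes (default 24).
#' @param n_phi Number of azimuthal nodes (default `2 n_theta`).
#' @return List of class `"sphere_grid"` with `points` (N x 3 unit vectors),
#'   `weights` (length N, summing to 4 pi) and `order` (exact polynomial
#'   degree).
#' @export
sphere_grid <- function(n_theta = 24, n_phi = 2 * n_theta) {
  gl <- gauss_legendre_cached(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- rep(phi, times = n_theta)
  pts <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  structure(list(points = pts, weights = w,
                 order = min(2 * n_theta - 1, n_phi - 1)),
            class = "sphere_grid")
}

#' Legendre polynomials
#'
#' Evaluates `P_0 ... P_lmax` at the given abscissae by the three-term
#' recurrence.
#'
#' @param t Numeric vector in `[-1, 1]`.
#' @param lmax Highest degree.
#' @return `length(t)` x `(lmax + 1)` matrix; column `l + 1` holds `P_l(t)`.
#' @export
legendre_poly <- function(t, lmax) {
  stopifnot(lmax >= 0)
  out <- matrix(0, length(t), lmax + 1L)
  out[, 1] <- 1
  if (lmax >= 1) out[, 2] <- t
  if (lmax >= 2) for (l in 2:lmax)
    out[, l + 1] <- ((2 * l - 1) * t * out[, l] - (l - 1) * out[, l - 1]) / l
  out
}

# fully normalized associated Legendre functions Pbar_l^m(x) for one order m,
# degrees l = m..lmax, including the Condon-Shortley phase; stable upward
# recurrence. Returns length(x) x (lmax - m + 1) matrix.
norm_assoc_legendre <- function(x, m, lmax) {
  s <- sqrt(pmax(1 - x^2, 0))
  # Pbar_m^m
  pmm <- rep(sqrt(1 / (4 * pi)), length(x))
  if (m > 0) for (k in 1:m)
    pmm <- -sqrt((2 * k + 1) / (2 * k)) * s * pmm
  out <- matrix(0, length(x), lmax - m + 1L)
  out[, 1] <- pmm
  if (lmax > m) {
    out[, 2] <- x * sqrt(2 * m + 3) * pmm
    if (lmax > m + 1) for (l in (m + 2):lmax) {
      a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
      b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
      out[, l - m + 1] <- a * (x * out[, l - m] - b * out[, l - m - 1])
    }
  }
  out
}

#' Real even-order spherical harmonic basis
#'
#' Evaluates the real, orthonormal spherical harmonics of even degree
#' `l = 0, 2, ..., lmax` at unit vectors, in the ordering used by MRtrix:
#' within each degree, `m = -l, ..., -1, 0, 1, ..., l` with
#' `Y_{l,-m} = sqrt(2) Pbar_l^m sin(m phi)` and
#' `Y_{l,m} = sqrt(2) Pbar_l^m cos(m phi)` for `m > 0`.
#'
#' @param points N x 3 matrix of unit vectors.
#' @param lmax Even maximum degree.
#' @return N x `(lmax + 1)(lmax + 2)/2` matrix; columns are annotated with
#'   attributes `l` and `m`.
#' @export
sh_basis <- function(points, lmax) {
  if (lmax %% 2 != 0) stop("'lmax' must be even", call. = FALSE)
  points <- matrix(points, ncol = 3)
  x <- points[, 3]                       # cos(theta)
  phi <- atan2(points[, 2], points[, 1])
  ncoef <- (lmax + 1) * (lmax + 2) / 2
  out <- matrix(0, nrow(points), ncoef)
  ls <- integer(ncoef); ms <- integer(ncoef)
  col <- 1L
  degs <- seq(0, lmax, by = 2)
  plm <- lapply(0:lmax, function(m) norm_assoc_legendre(x, m, lmax))
  for (l in degs) {
    for (m in -l:l) {
      am <- abs(m)
      p <- plm[[am + 1]][, l - am + 1]
      out[, col] <- if (m < 0) sqrt(2) * p * sin(am * phi)
                    else if (m == 0) p
                    else sqrt(2) * p * cos(m * phi)
      ls[col] <- l; ms[col] <- m; col <- col + 1L
    }
  }
  attr(out, "l") <- ls; attr(out, "m") <- ms
  out
}

# inverse-square Coulomb energy of the antipodally symmetrized point set,
# and the repulsive force on each point
.repulsion_energy <- function(P) {
  n <- nrow(P)
  e <- 0
  for (i in seq_len(n - 1)) {
    dplus <- sweep(P[(i + 1):n, , drop = FALSE], 2, P[i, ])
    dminus <- sweep(-P[(i + 1):n, , drop = FALSE], 2, P[i, ])
    e <- e + sum(1 / pmax(rowSums(dplus^2), 1e-12)) +
      sum(1 / pmax(rowSums(dminus^2), 1e-12))
  }
  e
}

.repulsion_force <- function(P) {
  n <- nrow(P)
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    dplus <- sweep(-P[-i, , drop = FALSE], 2, -P[i, ])     # x_i - x_j
    dminus <- sweep(P[-i, , drop = FALSE], 2, -P[i, ])     # x_i + x_j
    r2p <- pmax(rowSums(dplus^2), 1e-12)
    r2m <- pmax(rowSums(dminus^2), 1e-12)
    F[i, ] <- colSums(dplus / r2p^2) + colSums(dminus / r2m^2)
  }
  F
}

# Fibonacci hemisphere points: deterministic near-uniform start
.fibonacci_hemisphere <- function(n) {
  k <- seq_len(n)
  z <- (k - 0.5) / n
  phi <- 2 * pi * k * (sqrt(5) - 1) / 2
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Near-uniform gradient direction sets
#'
#' Generates `n` unit vectors per shell that are approximately uniformly
#' distributed under antipodal symmetry, by electrostatic repulsion of the
#' point set together with its antipodes, started from a seeded random
#' configuration. The result is reordered by a farthest-point criterion so
#' that any prefix of the first `k` directions is itself near-uniform
#' (nested designs for subsampling studies). Deterministic given the seed.
#'
#' @param n_per_shell Directions per shell (at least 6).
#' @param bvalues Non-zero shell b-values, s/mm^2.
#' @param seed Integer seed for the initial configuration.
#' @param n_b0 Number of b = 0 measurements prepended (default 1).
#' @param iterations Repulsion iterations (default 400).
#' @return A [gradient_scheme()] whose non-zero shells share the direction
#'   set.
#' @export
uniform_sphere_scheme <- function(n_per_shell, bvalues, seed = 1, n_b0 = 1,
                                  iterations = 400) {
  stopifnot(n_per_shell >= 6, length(bvalues) >= 1)
  dirs <- uniform_directions(n_per_shell, seed = seed, iterations = iterations)
  bval <- c(rep(0, n_b0), rep(bvalues, each = n_per_shell))
  dmat <- rbind(matrix(0, n_b0, 3),
                do.call(rbind, rep(list(dirs), length(bvalues))))
  gradient_scheme(bval, dmat, b_unit = "s/mm2")
}

#' @rdname uniform_sphere_scheme
#' @param n Number of directions.
#' @return `uniform_directions`: an `n` x 3 matrix of unit vectors.
#' @export
uniform_directions <- function(n, seed = 1, iterations = 400) {
  key <- sprintf("dirs_%d_%d_%d", n, seed, iterations)
  cached <- .mcsmt_cache[[key]]
  if (!is.null(cached)) return(cached)
  local_seed(seed)
  # seeded random rotation of a Fibonacci hemisphere start, then
  # energy-monitored repulsion descent with adaptive step
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  P <- .fibonacci_hemisphere(n) %*% Q
  E <- .repulsion_energy(P)
  delta <- 0.1 / sqrt(n)
  for (it in seq_len(iterations)) {
    F <- .repulsion_force(P)
    F <- F - P * rowSums(F * P)            # tangential component
    fmax <- max(sqrt(rowSums(F^2)))
    if (fmax < 1e-14) break
    cand <- P + (delta / fmax) * F
    cand <- cand / sqrt(rowSums(cand^2))
    Ec <- .repulsion_energy(cand)
    if (Ec < E) { P <- cand; E <- Ec; delta <- delta * 1.2 }
    else delta <- delta / 2
    if (delta < 1e-8) break
  }
  P <- farthest_point_order(P)
  .mcsmt_cache[[key]] <- P
  P
}

.mcsmt_cache <- new.env(parent = emptyenv())

# memoized Gauss-Legendre rules (node computation is not free and the same
# rules recur throughout)
gauss_legendre_cached <- function(n, a, b) {
  key <- sprintf("gl_%d_%g_%g", n, a, b)
  g <- .mcsmt_cache[[key]]
  if (is.null(g)) {
    g <- pracma::gaussLegendre(n, a, b)
    .mcsmt_cache[[key]] <- g
  }
  g
}

# reorder points so every prefix is well spread: greedy maximization of the
# minimum antipodal angle to already-chosen points
farthest_point_order <- function(P) {
  n <- nrow(P)
  absdot <- abs(P %*% t(P))
  chosen <- 1L
  remaining <- setdiff(seq_len(n), chosen)
  maxdot <- absdot[, 1L]   # closeness of each point to the chosen set
  while (length(remaining) > 0) {
    nxt <- remaining[which.min(maxdot[remaining])]
    chosen <- c(chosen, nxt)
    remaining <- setdiff(remaining, nxt)
    maxdot <- pmax(maxdot, absdot[, nxt])
  }
  P[chosen, , drop = FALSE]
}

#' Spherical-cap discrepancy of a direction set
#'
#' Monte-Carlo estimate of the antipodally symmetrized spherical-cap
#' discrepancy: the maximum absolute difference between the fraction of
#' directions falling in a random cap (counting antipodes) and the cap's
#' area fraction.
#'
#' @param dirs N x 3 matrix of unit vectors.
#' @param n_caps Number of random caps tested.
#' @param seed Seed for the random caps.
#' @return Scalar discrepancy estimate.
#' @export
cap_discrepancy <- function(dirs, n_caps = 2000, seed = 7) {
  local_seed(seed)
  C <- matrix(stats::rnorm(3 * n_caps), n_caps, 3)
  C <- C / sqrt(rowSums(C^2))
  h <- stats::runif(n_caps)          # cap height in [0, 1]: antipodal pair of caps
  absdot <- abs(dirs %*% t(C))
  thresh <- matrix(rep(1 - h, each = nrow(dirs)), nrow(dirs))
  frac <- colMeans(absdot >= thresh)
  max(abs(frac - h))
}

# smallest pairwise angle (degrees) of a direction set under antipodal
# identification
min_pairwise_angle <- function(dirs) {
  d <- abs(dirs %*% t(dirs))
  diag(d) <- 0
  acos(pmin(max(d), 1)) * 180 / pi
}
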