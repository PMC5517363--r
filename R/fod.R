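# Stage-2 orientation analysis: spherical deconvolution with the fitted
# voxel-wise two-compartment kernel, and the orientation dispersion entropy.

#' Rotational harmonics of the microscopic signal kernel
#'
#' Funk-Hecke coefficients of the two-compartment impulse response at each
#' b-value: `c_l(b) = 2 pi integral_{-1}^{1} h_b(t) P_l(t) dt`, computed by
#' Gauss-Legendre quadrature. Odd degrees vanish by antipodal symmetry, and
#' `c_0(b) = 4 pi * mean_total(b)` (the order-0 coefficient is the spherical
#' mean).
#'
#' @param params A [micro_params()] object (the voxel's fitted kernel).
#' @param b Shell b-values, ms/micrometre^2.
#' @param lmax Even maximum degree.
#' @param n_nodes Quadrature nodes (default 64).
#' @return `length(b)` x `(lmax + 1)` matrix; column `l + 1` holds `c_l`.
#' @export
kernel_rotational_harmonics <- function(params, b, lmax, n_nodes = 64) {
  stopifnot(inherits(params, "micro_params"))
  if (lmax %% 2 != 0) stop("'lmax' must be even", call. = FALSE)
  gl <- gauss_legendre_cached(n_nodes, -1, 1)
  P <- legendre_poly(gl$x, lmax)
  out <- matrix(0, length(b), lmax + 1L)
  for (i in seq_along(b)) {
    h <- compartment_signal(b[i], gl$x, params)
    out[i, ] <- 2 * pi * as.vector(crossprod(P, gl$w * h))
  }
  if (lmax >= 1) out[, seq(2, lmax + 1, by = 2)] <- 0
  out
}

# construct a fod object from grid values (clipped + normalized) and their SH
# projection
.make_fod <- function(values, grid, lmax, sh_raw = NULL) {
  values <- pmax(values, 0)
  mass <- sum(grid$weights * values)
  if (mass <= 0) stop("degenerate FOD: zero mass on the grid", call. = FALSE)
  values <- values / mass
  Y <- sh_basis(grid$points, lmax)
  sh <- as.vector(crossprod(Y, grid$weights * values))
  attributes(sh) <- attributes(sh)["names"]
  structure(list(sh = sh, lmax = lmax, grid = grid, values = values,
                 sh_raw = sh_raw,
                 l = attr(Y, "l"), m = attr(Y, "m")),
            class = "fod")
}

#' @export
print.fod <- function(x, ...) {
  pk <- fod_peak(x)
  cat(sprintf("Fibre orientation distribution (lmax = %d, %d grid points)\n",
              x$lmax, nrow(x$grid$points)))
  cat(sprintf("  integral = %.6f, min = %.2e, peak axis = (%.3f, %.3f, %.3f)\n",
              sum(x$grid$weights * x$values), min(x$values),
              pk[1], pk[2], pk[3]))
  cat(sprintf("  orientation dispersion entropy = %.4f nats\n",
              orientation_dispersion_entropy(x)))
  invisible(x)
}

#' Construct an FOD from an analytic density
#'
#' Evaluates a density on a spherical quadrature grid and stores it together
#' with its even-order spherical-harmonic projection. Useful for ground-truth
#' FODs (e.g. [watson_mixture()] densities).
#'
#' @param density Either a [watson_mixture()] or a function of an N x 3
#'   matrix of unit vectors returning density values.
#' @param lmax Even maximum SH degree (default 16).
#' @param grid A [sphere_grid()]; default 48 x 96 (fine enough for sharply
#'   peaked densities).
#' @return An object of class `"fod"`.
#' @export
fod_from_density <- function(density, lmax = 16, grid = sphere_grid(48)) {
  f <- if (inherits(density, "watson_mixture"))
    function(p) mixture_density(density, p) else density
  vals <- f(grid$points)
  if (any(vals < -1e-8)) stop("density must be non-negative", call. = FALSE)
  .make_fod(vals, grid, lmax)
}

#' Spherical deconvolution of the fibre orientation distribution
#'
#' Recovers the voxel's fibre orientation distribution from its
#' diffusion-weighted measurements, given the fitted microscopic parameters:
#' a linear least-squares fit in the even-order real spherical-harmonic basis
#' with per-shell Funk-Hecke kernel coefficients, followed by alternating
#' projection onto the set of densities that are non-negative on the
#' evaluation grid and integrate to one. Deterministic.
#'
#' @param signals Normalized diffusion signals, one per measurement in
#'   `scheme` (b = 0 entries are ignored).
#' @param scheme A [gradient_scheme()].
#' @param params The voxel's [micro_params()].
#' @param lmax Even maximum degree; default 8 when every shell has at least
#'   60 directions, else 4. Reduced automatically (with a warning) if the
#'   directions cannot support it.
#' @param grid Evaluation/projection [sphere_grid()] (default 24 x 48,
#'   1152 points).
#' @param max_iter,tol Alternating-projection controls.
#' @return An object of class `"fod"`: `sh` (projected SH coefficients,
#'   MRtrix-style real even-order ordering), `sh_raw` (unconstrained
#'   least-squares coefficients), grid `values` (non-negative, unit mass),
#'   and the grid itself.
#' @export
deconvolve_fod <- function(signals, scheme, params, lmax = NULL,
                           grid = sphere_grid(24), max_iter = 200,
                           tol = 1e-10) {
  stopifnot(inherits(scheme, "gradient_scheme"), inherits(params, "micro_params"))
  b0 <- is_b0_measurement(scheme)
  use <- which(!b0)
  stopifnot(length(signals) == length(scheme$bvalues))
  if (is.null(lmax))
    lmax <- if (min(scheme$shells$n[!scheme$shells$is_b0]) >= 60) 8 else 4
  if (lmax %% 2 != 0) stop("'lmax' must be even", call. = FALSE)
  n_indep <- length(use)
  while ((lmax + 1) * (lmax + 2) / 2 > n_indep && lmax > 0) lmax <- lmax - 2
  dirs <- scheme$directions[use, , drop = FALSE]
  shell_of <- scheme$shell_id[use]
  shells <- sort(unique(shell_of))
  bvals <- scheme$shells$nominal_b[shells]
  C <- kernel_rotational_harmonics(params, bvals, lmax)
  Y <- sh_basis(dirs, lmax)
  ldeg <- attr(Y, "l")
  A <- Y * C[match(shell_of, shells), ldeg + 1L]
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    while (qrA$rank < (lmax + 1) * (lmax + 2) / 2 && lmax > 0) {
      lmax <- lmax - 2
      warning("rank-deficient deconvolution system; reducing lmax to ", lmax)
      C <- kernel_rotational_harmonics(params, bvals, lmax)
      Y <- sh_basis(dirs, lmax)
      ldeg <- attr(Y, "l")
      A <- Y * C[match(shell_of, shells), ldeg + 1L]
      qrA <- qr(A)
    }
  }
  f <- qr.coef(qrA, signals[use])
  f[is.na(f)] <- 0
  sh_raw <- f
  # alternating projection: SH-representable <-> {p >= 0 on grid, mass 1}
  Yg <- sh_basis(grid$points, lmax)
  w <- grid$weights
  for (it in seq_len(max_iter)) {
    p <- as.vector(Yg %*% f)
    neg <- min(p)
    p <- pmax(p, 0)
    mass <- sum(w * p)
    if (mass <= 0) { p <- rep(1 / (4 * pi), length(p)); mass <- 1 }
    else p <- p / mass
    f_new <- as.vector(crossprod(Yg, w * p))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (neg >= -tol && abs(mass - 1) < tol && delta < tol) break
  }
  p <- pmax(as.vector(Yg %*% f), 0)
  .make_fod(p, grid, lmax, sh_raw = sh_raw)
}

#' Orientation dispersion entropy
#'
#' Kullback-Leibler divergence of the fibre orientation distribution from the
#' uniform spherical density `q = 1/(4 pi)`:
#' `H(p) = integral p(omega) ln(p(omega)/q(omega)) d omega`, evaluated by the
#' FOD's quadrature grid. Zero for an isotropic distribution, large for
#' coherent single-fibre voxels; `p ln p` terms at `p <= 0` contribute zero
#' (limit convention).
#'
#' @param fod An object of class `"fod"`.
#' @return Entropy in nats, `>= 0` up to quadrature error.
#' @export
orientation_dispersion_entropy <- function(fod) {
  stopifnot(inherits(fod, "fod"))
  p <- fod$values
  w <- fod$grid$weights
  mass <- sum(w * p)
  if (abs(mass - 1) > 1e-6)
    stop("FOD is not normalized (integral = ", signif(mass, 8), ")", call. = FALSE)
  pos <- p > 0
  sum(w[pos] * p[pos] * log(4 * pi * p[pos]))
}

#' Peak axis of an FOD
#'
#' Locates the grid maximum of the FOD on a fine evaluation grid (local grid
#' maxima only; no continuous peak refinement).
#'
#' @param fod An object of class `"fod"`.
#' @param n_theta Polar resolution of the search grid (default 64).
#' @return Unit 3-vector of the strongest peak (sign is arbitrary: the FOD is
#'   antipodally symmetric).
#' @export
fod_peak <- function(fod, n_theta = 64) {
  stopifnot(inherits(fod, "fod"))
  g <- sphere_grid(n_theta)
  vals <- as.vector(sh_basis(g$points, fod$lmax) %*% fod$sh)
  g$points[which.max(vals), ]
}

#' Deconvolve FODs and entropy over a fitted volume
#'
#' Runs [deconvolve_fod()] for every fitted voxel of an [mcsmt()] result and
#' assembles an SH coefficient volume and an orientation dispersion entropy
#' map.
#'
#' @param dataset The normalized [dwi_dataset()] the fit came from.
#' @param fit The corresponding `"mcsmt"` object.
#' @param lmax,grid Passed to [deconvolve_fod()].
#' @return List with `sh` (4-D array, last axis the SH coefficients),
#'   `entropy` (3-D array), `lmax`.
#' @export
fod_volume <- function(dataset, fit, lmax = NULL, grid = sphere_grid(24)) {
  stopifnot(inherits(dataset, "dwi_dataset"), inherits(fit, "mcsmt"))
  if (!dataset$normalized) dataset <- normalize_signal(dataset)
  d <- dim(dataset$signal)
  sig <- matrix(dataset$signal, prod(d[1:3]), d[4])
  idx <- which(as.vector(fit$mask) & !is.na(as.vector(fit$maps$v_int)))
  sh_list <- NULL
  entropy <- array(NA_real_, d[1:3])
  sh_arr <- NULL
  for (i in idx) {
    p <- micro_params(fit$maps$v_int[i], fit$maps$lambda[i], fit$lambda_free)
    fod <- deconvolve_fod(sig[i, ], dataset$scheme, p, lmax = lmax, grid = grid)
    if (is.null(sh_arr))
      sh_arr <- array(NA_real_, c(d[1:3], length(fod$sh)))
    vox <- arrayInd(i, d[1:3])
    sh_arr[vox[1], vox[2], vox[3], ] <- fod$sh
    entropy[i] <- orientation_dispersion_entropy(fod)
  }
  list(sh = sh_arr, entropy = entropy,
       lmax = if (length(idx)) fod$lmax else lmax)
}
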