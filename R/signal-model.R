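#' Microscopic model parameters
#'
#' Container for the state of the two-compartment microscopic diffusion model:
#' the intra-neurite volume fraction, the intrinsic diffusivity shared by the
#' two compartments, and the free-water diffusivity that bounds it. All
#' diffusivities are in micrometre^2/ms so that `b * lambda` is dimensionless
#' when b is given in ms/micrometre^2.
#'
#' The transverse extra-neurite diffusivity is not a free parameter: it is tied
#' to `(1 - v_int) * lambda` by a first-order tortuosity approximation for
#' diffusion around randomly placed impermeable parallel cylinders, and the
#' extra-neurite mean diffusivity `(1 - 2/3 v_int) * lambda` follows from it.
#'
#' @param v_int Intra-neurite (stick) signal volume fraction, in `[0, 1]`.
#'   Myelin water is excluded by assumption (short T2).
#' @param lambda Intrinsic diffusivity parallel to the neurites,
#'   micrometre^2/ms, in `[0, lambda_free]`.
#' @param lambda_free Free-water diffusivity bound, micrometre^2/ms. Defaults
#'   to the body-temperature value; see [lambda_free_default()].
#' @return An object of class `"micro_params"` with elements `v_int`, `lambda`,
#'   `lambda_free`, and the derived `lambda_perp_ext` and `lambda_mean_ext`.
#' @examples
#' p <- micro_params(v_int = 0.6, lambda = 2)
#' p$lambda_perp_ext   # (1 - 0.6) * 2 = 0.8
#' @export
micro_params <- function(v_int, lambda, lambda_free = lambda_free_default()) {
  stopifnot(length(v_int) == 1L, length(lambda) == 1L, length(lambda_free) == 1L)
  if (!is.finite(v_int) || v_int < 0 || v_int > 1)
    stop("'v_int' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0)
    stop("'lambda' must be non-negative", call. = FALSE)
  if (lambda > lambda_free + 1e-12)
    stop("'lambda' must not exceed 'lambda_free' (", lambda_free, ")", call. = FALSE)
  structure(list(
    v_int = v_int, lambda = min(lambda, lambda_free), lambda_free = lambda_free,
    lambda_perp_ext = tortuosity_transverse(v_int, lambda),
    lambda_mean_ext = extraneurite_mean_diffusivity(v_int, lambda)
  ), class = "micro_params")
}

#' @export
print.micro_params <- function(x, ...) {
  cat("Two-compartment microscopic parameters (um^2/ms):\n")
  cat(sprintf("  v_int           = %.4f\n", x$v_int))
  cat(sprintf("  lambda          = %.4f  (bound lambda_free = %.2f)\n",
              x$lambda, x$lambda_free))
  cat(sprintf("  lambda_perp_ext = %.4f   [tortuosity (1 - v_int) lambda]\n",
              x$lambda_perp_ext))
  cat(sprintf("  lambda_mean_ext = %.4f   [(1 - 2/3 v_int) lambda]\n",
              x$lambda_mean_ext))
  invisible(x)
}

#' Default free-water diffusivity
#'
#' Temperature-dependent self-diffusion coefficient of free water used as the
#' upper bound for the intrinsic diffusivity: about 3.05 um^2/ms at 37 degrees
#' Celsius (in vivo) and about 1.88 um^2/ms at 17 degrees Celsius (typical
#' ex vivo bore temperature).
#'
#' @param setting `"invivo"` (37 C) or `"exvivo"` (17 C).
#' @return Diffusivity in micrometre^2/ms.
#' @export
lambda_free_default <- function(setting = c("invivo", "exvivo")) {
  switch(match.arg(setting), invivo = 3.05, exvivo = 1.88)
}

# error function via the normal CDF; vectorized
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Stick compartment signal
#'
#' Signal from the intra-neurite (stick) compartment: a cylinder with zero
#' transverse diffusivity, `exp(-b t^2 lambda)` where `t` is the cosine of the
#' angle between gradient direction and fibre orientation.
#'
#' @param b Diffusion weighting, ms/micrometre^2 (non-negative).
#' @param t Spherical distance `<g, omega>` in `[-1, 1]`.
#' @param lambda Intrinsic diffusivity, micrometre^2/ms.
#' @return Signal attenuation in `(0, 1]`. Vectorized over the arguments.
#' @export
stick_signal <- function(b, t, lambda) {
  if (any(abs(t) > 1 + 1e-9)) stop("'t' must lie in [-1, 1]", call. = FALSE)
  if (any(b < 0) || any(lambda < 0)) stop("'b' and 'lambda' must be non-negative", call. = FALSE)
  t <- pmin(pmax(t, -1), 1)
  exp(-b * t^2 * lambda)
}

#' Zeppelin compartment signal
#'
#' Signal from an axially symmetric microscopic tensor (zeppelin) with
#' longitudinal diffusivity `lambda` and transverse diffusivity `lambda_perp`:
#' `exp(-b t^2 lambda) * exp(-b (1 - t^2) lambda_perp)`.
#'
#' @inheritParams stick_signal
#' @param lambda_perp Transverse diffusivity, `0 <= lambda_perp <= lambda`.
#' @return Signal attenuation in `(0, 1]`.
#' @export
zeppelin_signal <- function(b, t, lambda, lambda_perp) {
  if (any(lambda_perp > lambda + 1e-12))
    stop("'lambda_perp' must not exceed 'lambda'", call. = FALSE)
  if (any(lambda_perp < 0)) stop("'lambda_perp' must be non-negative", call. = FALSE)
  if (any(abs(t) > 1 + 1e-9)) stop("'t' must lie in [-1, 1]", call. = FALSE)
  t <- pmin(pmax(t, -1), 1)
  exp(-b * t^2 * lambda) * exp(-b * (1 - t^2) * lambda_perp)
}

#' Two-compartment microscopic signal
#'
#' Volume-fraction weighted sum of the stick (intra-neurite) and zeppelin
#' (extra-neurite) signals, with the zeppelin transverse diffusivity given by
#' the tortuosity approximation `(1 - v_int) * lambda`.
#'
#' @inheritParams stick_signal
#' @param params A [micro_params()] object.
#' @return Signal attenuation in `(0, 1]`.
#' @export
compartment_signal <- function(b, t, params) {
  stopifnot(inherits(params, "micro_params"))
  params$v_int * stick_signal(b, t, params$lambda) +
    (1 - params$v_int) *
      zeppelin_signal(b, t, params$lambda, params$lambda_perp_ext)
}

#' Tortuosity approximation for the extra-neurite transverse diffusivity
#'
#' First-order effective-medium result for diffusion perpendicular to randomly
#' placed impermeable parallel cylinders: `lambda_perp_ext = (1 - v_int) * lambda`.
#'
#' @inheritParams micro_params
#' @return Transverse extra-neurite diffusivity, micrometre^2/ms.
#' @export
tortuosity_transverse <- function(v_int, lambda) {
  if (any(v_int < 0 | v_int > 1)) stop("'v_int' must lie in [0, 1]", call. = FALSE)
  if (any(lambda < 0)) stop("'lambda' must be non-negative", call. = FALSE)
  (1 - v_int) * lambda
}

#' Extra-neurite microscopic mean diffusivity
#'
#' Mean diffusivity of the extra-neurite water pool,
#' `(lambda_par + 2 lambda_perp)/3` with `lambda_par = lambda` and the
#' tortuosity transverse diffusivity, which simplifies to
#' `(1 - 2/3 v_int) * lambda`. A useful cerebrospinal-fluid biomarker: it
#' approaches the free-water diffusivity where `v_int` tends to zero.
#'
#' @inheritParams micro_params
#' @return Mean extra-neurite diffusivity, micrometre^2/ms.
#' @export
extraneurite_mean_diffusivity <- function(v_int, lambda) {
  if (any(v_int < 0 | v_int > 1)) stop("'v_int' must lie in [0, 1]", call. = FALSE)
  if (any(lambda < 0)) stop("'lambda' must be non-negative", call. = FALSE)
  (1 - (2 / 3) * v_int) * lambda
}

# sqrt(pi) * erf(sqrt(x)) / (2 sqrt(x)) with a series for small x; the 0/0 at
# x = 0 is removable: 1 - x/3 + x^2/10 - ...
erf_mean_kernel <- function(x) {
  if (any(x < -1e-12)) stop("negative erf argument: b*lambda must be >= 0", call. = FALSE)
  x <- pmax(x, 0)
  out <- x  # preserves dim attributes
  small <- x < 1e-6
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10
  xl <- x[!small]
  out[!small] <- sqrt(pi) * erf(sqrt(xl)) / (2 * sqrt(xl))
  out
}

#' Spherical mean of the stick signal
#'
#' Closed form of the orientation average of the stick compartment at fixed b:
#' `sqrt(pi) * erf(sqrt(b lambda)) / (2 sqrt(b lambda))`, with a Taylor series
#' for small `b lambda` where the expression is 0/0.
#'
#' @inheritParams stick_signal
#' @return Mean signal in `(0, 1]`. Vectorized.
#' @export
mean_stick <- function(b, lambda) {
  if (any(b < 0) || any(lambda < 0)) stop("'b' and 'lambda' must be non-negative", call. = FALSE)
  erf_mean_kernel(b * lambda)
}

#' Spherical mean of the zeppelin signal
#'
#' Closed form of the orientation average of the zeppelin compartment:
#' `exp(-b lambda_perp) * sqrt(pi) * erf(sqrt(b (lambda - lambda_perp))) /
#' (2 sqrt(b (lambda - lambda_perp)))`, series-protected near
#' `lambda_perp = lambda` (isotropic limit `exp(-b lambda)`).
#'
#' @inheritParams zeppelin_signal
#' @return Mean signal in `(0, 1]`. Vectorized.
#' @export
mean_zeppelin <- function(b, lambda, lambda_perp) {
  if (any(lambda_perp > lambda + 1e-12))
    stop("'lambda_perp' must not exceed 'lambda'", call. = FALSE)
  if (any(lambda_perp < 0)) stop("'lambda_perp' must be non-negative", call. = FALSE)
  exp(-b * lambda_perp) * erf_mean_kernel(b * pmax(lambda - lambda_perp, 0))
}

#' Spherical mean of the two-compartment model
#'
#' Orientation-averaged signal of the full microscopic model at diffusion
#' weighting b: the volume-fraction weighted sum of the stick and zeppelin
#' spherical means (the spherical mean is linear over compartments). By the
#' spherical mean invariance property this is the expected per-shell mean
#' signal for *any* fibre orientation distribution.
#'
#' @param b Diffusion weighting(s), ms/micrometre^2.
#' @param params A [micro_params()] object.
#' @return Mean signal(s) in `(0, 1]`, same length as `b`.
#' @examples
#' mean_total(c(1, 2, 3), micro_params(0.6, 2))
#' @export
mean_total <- function(b, params) {
  stopifnot(inherits(params, "micro_params"))
  params$v_int * mean_stick(b, params$lambda) +
    (1 - params$v_int) *
      mean_zeppelin(b, params$lambda, params$lambda_perp_ext)
}

#' Quadrature oracle for spherical means
#'
#' Computes the orientation average `integral_0^{pi/2} h_b(cos theta)
#' sin(theta) d theta` of an antipodally symmetric signal profile by
#' Gauss-Legendre quadrature on `u = cos(theta)` over `[0, 1]`. Intended as an
#' independent numerical check of the closed-form means.
#'
#' @param signal_fn Function of `t = cos(theta)` in `[0, 1]` returning the
#'   signal `h_b(t)`; must be vectorized.
#' @param n_nodes Number of Gauss-Legendre nodes (default 64).
#' @return The spherical mean signal.
#' @export
spherical_mean_oracle <- function(signal_fn, n_nodes = 64) {
  stopifnot(n_nodes >= 64)
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  vals <- signal_fn(gl$x)
  if (any(!is.finite(vals))) stop("non-finite integrand in spherical mean oracle", call. = FALSE)
  sum(gl$w * vals)
}
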