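# Stage-1 estimator: spherical mean signals per shell, Rician bias
# adjustment, and the constrained least-squares fit of (v_int, lambda).

#' Estimate the noise level from repeated b = 0 images
#'
#' Computes the per-voxel standard deviation over the (normalized) b = 0
#' frames and returns its median over the mask as a single scalar noise level
#' sigma, in the same units as the normalized signal (so sigma is 1/SNR at
#' the b = 0 level).
#'
#' @param dataset A normalized [dwi_dataset()] with at least two b = 0 frames.
#' @param sigma Optional user-supplied sigma; returned unchanged when given.
#' @return Scalar sigma estimate.
#' @export
estimate_noise_sigma <- function(dataset, sigma = NULL) {
  if (!is.null(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
    return(sigma)
  }
  stopifnot(inherits(dataset, "dwi_dataset"))
  if (!dataset$normalized)
    dataset <- normalize_signal(dataset)
  b0 <- is_b0_measurement(dataset$scheme)
  if (sum(b0) < 2L)
    stop("noise estimation requires at least two b = 0 frames; ",
         "supply 'sigma' directly otherwise", call. = FALSE)
  d <- dim(dataset$signal)
  mat <- matrix(dataset$signal, prod(d[1:3]), d[4])[as.vector(dataset$mask), b0,
                                                    drop = FALSE]
  sds <- apply(mat, 1L, stats::sd)
  n <- sum(b0)
  # small-sample corrections: c4 unbiases the Gaussian sd, and sqrt(1 - 1/n)
  # undoes the shrinkage from dividing each frame by the frames' own mean
  c4 <- sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
  stats::median(sds, na.rm = TRUE) / (c4 * sqrt(1 - 1 / n))
}

#' Adjust magnitude signals for the Rician noise floor
#'
#' Method-of-moments adjustment based on the second-moment identity
#' `E[m^2] = A^2 + 2 sigma^2` of the Rician distribution:
#' `m_adj = sqrt(max(m^2 - 2 sigma^2, 0))`, applied per measurement before
#' spherical averaging. `sigma = 0` is the identity.
#'
#' @param signal Numeric vector/array of magnitude signals.
#' @param sigma Noise standard deviation (same units as `signal`).
#' @return Adjusted signals, same shape as the input.
#' @export
correct_rician_bias <- function(signal, sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(signal)
  out <- sqrt(pmax(signal^2 - 2 * sigma^2, 0))
  attributes(out) <- attributes(signal)
  out
}

#' Per-shell spherical mean signals
#'
#' Averages the (optionally bias-adjusted) normalized signals over the
#' gradient directions of each non-zero shell, voxel by voxel. The b = 0
#' shell is excluded: its mean is 1 by construction after normalization.
#'
#' @param dataset A normalized [dwi_dataset()].
#' @param sigma Rician noise level used for bias adjustment before averaging;
#'   0 disables the adjustment.
#' @return Object of class `"shell_means"`: list with `b` (non-zero nominal
#'   shell b-values, ms/um^2), `n_dir` (directions per shell), `means`
#'   (voxels x shells matrix, `NA` outside the mask), `mask`, `dim` (spatial
#'   shape) and `sigma`.
#' @export
shell_means <- function(dataset, sigma = 0) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  if (!dataset$normalized)
    stop("'dataset' must be normalized first (see normalize_signal)", call. = FALSE)
  scheme <- dataset$scheme
  nz <- which(!scheme$shells$is_b0)
  if (length(nz) == 0L) stop("no non-zero b-shells in the dataset", call. = FALSE)
  empty <- scheme$shells$n[nz] == 0L
  if (any(empty)) {
    warning("skipping empty shell(s) at b = ",
            paste(scheme$shells$nominal_b[nz][empty] * 1000, collapse = ", "),
            " s/mm2")
    nz <- nz[!empty]
  }
  d <- dim(dataset$signal)
  mat <- matrix(dataset$signal, prod(d[1:3]), d[4])
  if (sigma > 0) mat <- correct_rician_bias(mat, sigma)
  means <- vapply(nz, function(k) {
    rowMeans(mat[, scheme$shell_id == k, drop = FALSE])
  }, numeric(nrow(mat)))
  means <- matrix(means, nrow = nrow(mat))
  means[!as.vector(dataset$mask), ] <- NA_real_
  structure(list(b = scheme$shells$nominal_b[nz],
                 n_dir = scheme$shells$n[nz],
                 means = means, mask = dataset$mask, dim = d[1:3],
                 sigma = sigma),
            class = "shell_means")
}

# model spherical means for vectors of candidate (v, lam) across shells b;
# returns length(v) x length(b) matrix
mean_total_grid <- function(b, v, lam) {
  bl <- outer(lam, b)                       # b * lambda
  stick <- erf_mean_kernel(bl)
  lperp <- (1 - v) * lam
  zep <- exp(-outer(lperp, b)) * erf_mean_kernel(outer(lam - lperp, b))
  v * stick + (1 - v) * zep
}

#' Fit the microscopic model to one voxel's shell means
#'
#' Minimizes the sum of squared differences between observed and model
#' spherical mean signals over the box `v_int` in `[0, 1]`,
#' `lambda` in `[0, lambda_free]`: a coarse lattice search (default 21 x 21)
#' followed by bounded quasi-Newton refinement from the best lattice point.
#' Fully deterministic. At least two non-zero shells are required; with one
#' shell the problem is underdetermined.
#'
#' @param b Non-zero shell b-values, ms/micrometre^2.
#' @param ebar Observed spherical mean signals, one per shell.
#' @param lambda_free Upper bound on the intrinsic diffusivity, um^2/ms.
#' @param weights Per-shell weights in the objective (default equal).
#' @param grid_size Lattice points per parameter for the coarse search.
#' @param refine_tol Objective tolerance of the local refinement.
#' @return List of class `"mcsmt_voxel"`: `params` ([micro_params()]), `rss`,
#'   `boundary` (named logical: `v_lo`, `v_hi`, `lambda_lo`, `lambda_hi`),
#'   `iterations`, `skipped`.
#' @examples
#' b <- c(1, 2, 3)
#' truth <- micro_params(0.6, 2)
#' fit_voxel(b, mean_total(b, truth))$params
#' @export
fit_voxel <- function(b, ebar, lambda_free = lambda_free_default(),
                      weights = NULL, grid_size = 21, refine_tol = 1e-10) {
  b <- as.numeric(b); ebar <- as.numeric(ebar)
  stopifnot(length(b) == length(ebar))
  if (length(unique(round(b, 8))) < 2L)
    stop("SMT needs two or more distinct non-zero b-shells: ",
         "the (v_int, lambda) estimation problem is underdetermined with ",
         length(unique(round(b, 8))), call. = FALSE)
  if (all(is.na(ebar)))
    return(structure(list(params = NULL, rss = NA_real_,
                          boundary = c(v_lo = NA, v_hi = NA,
                                       lambda_lo = NA, lambda_hi = NA),
                          iterations = 0L, skipped = TRUE),
                     class = "mcsmt_voxel"))
  if (any(!is.finite(ebar)))
    stop("non-finite shell mean signal", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(b))
  stopifnot(length(weights) == length(b), all(weights >= 0))

  vs <- seq(0, 1, length.out = grid_size)
  ls <- seq(0, lambda_free, length.out = grid_size)
  gv <- rep(vs, times = grid_size)
  gl <- rep(ls, each = grid_size)
  pred <- mean_total_grid(b, gv, gl)
  sse <- as.vector((pred - rep(ebar, each = length(gv)))^2 %*% weights)
  best <- which.min(sse)

  # lean scalar-parameter model evaluation for the refinement loop
  fk <- function(x) {  # sqrt(pi) erf(sqrt x)/(2 sqrt x), series-protected
    r <- x
    i <- x < 1e-6
    r[i] <- 1 - x[i] / 3 + x[i]^2 / 10
    xi <- x[!i]
    r[!i] <- sqrt(pi) * (2 * stats::pnorm(sqrt(2 * xi)) - 1) / (2 * sqrt(xi))
    r
  }
  model <- function(p) {
    v <- p[1]; lam <- p[2]; lperp <- (1 - v) * lam
    v * fk(b * lam) + (1 - v) * exp(-b * lperp) * fk(b * (lam - lperp))
  }
  obj <- function(p) sum(weights * (model(p) - ebar)^2)
  opt <- stats::optim(c(gv[best], gl[best]), obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(1, lambda_free),
                      control = list(factr = max(refine_tol / .Machine$double.eps / 1e4, 1),
                                     pgtol = 0, maxit = 200))
  # damped Gauss-Newton polish, projected into the box: quasi-Newton line
  # searches stall well above the precision the noiseless problem admits
  par <- opt$par; val <- opt$value; it_gn <- 0L
  resid <- function(p) sqrt(weights) * (model(p) - ebar)
  for (k in seq_len(60)) {
    r0 <- resid(par)
    h <- 1e-7
    J <- cbind((resid(pmin(pmax(par + c(h, 0), 0), c(1, lambda_free))) - r0) / h,
               (resid(pmin(pmax(par + c(0, h), 0), c(1, lambda_free))) - r0) / h)
    step <- tryCatch(qr.solve(J, -r0), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    improved <- FALSE
    for (damp in 2^-(0:8)) {
      cand <- pmin(pmax(par + damp * step, 0), c(1, lambda_free))
      v_cand <- obj(cand)
      if (v_cand < val) { par <- cand; val <- v_cand; improved <- TRUE; break }
    }
    it_gn <- k
    if (!improved || sqrt(sum(step^2)) < 1e-12 || val < refine_tol^2) break
  }
  if (val <= opt$value) opt <- list(par = par, value = val,
                                    counts = opt$counts + c(it_gn, 0))
  if (opt$value > sse[best]) {      # refinement must never lose to the lattice
    opt$par <- c(gv[best], gl[best]); opt$value <- sse[best]
  }
  v <- min(max(opt$par[1], 0), 1)
  lam <- min(max(opt$par[2], 0), lambda_free)
  tol_v <- 1e-6; tol_l <- 1e-6 * lambda_free
  structure(list(
    params = micro_params(v, lam, lambda_free),
    rss = opt$value,
    boundary = c(v_lo = v <= tol_v, v_hi = v >= 1 - tol_v,
                 lambda_lo = lam <= tol_l, lambda_hi = lam >= lambda_free - tol_l),
    iterations = unname(opt$counts[1]),
    skipped = FALSE), class = "mcsmt_voxel")
}

#' @export
print.mcsmt_voxel <- function(x, ...) {
  if (isTRUE(x$skipped)) { cat("Skipped voxel (all-NA shell means)\n"); return(invisible(x)) }
  print(x$params)
  cat(sprintf("  residual sum of squares = %.3g; at bound: %s\n", x$rss,
              if (any(x$boundary)) paste(names(x$boundary)[x$boundary], collapse = ", ")
              else "none"))
  invisible(x)
}

#' Multi-compartment spherical mean technique fit
#'
#' The main model-fitting entry point. For every voxel in the mask the
#' two-step SMT estimator is applied: (1) the T2-normalized signals are
#' averaged over the gradient directions of each non-zero b-shell, after a
#' method-of-moments adjustment for the Rician noise floor; (2) the
#' two-compartment spherical mean model is fitted to those shell means by
#' constrained least squares, giving the intra-neurite volume fraction
#' `v_int` and intrinsic diffusivity `lambda`, from which the tortuosity
#' transverse diffusivity and the extra-neurite mean diffusivity follow.
#'
#' Estimates at the box bounds are reported (not censored) and flagged:
#' cerebrospinal fluid legitimately sits at `v_int = 0`,
#' `lambda = lambda_free`.
#'
#' @param dataset A [dwi_dataset()]; normalized automatically if needed.
#' @param lambda_free Free-water diffusivity bound, um^2/ms
#'   (see [lambda_free_default()]).
#' @param sigma Rician noise level of the normalized signal; estimated from
#'   repeated b = 0 frames when `NULL` and `bias_correct = TRUE`.
#' @param bias_correct Apply the Rician bias adjustment before averaging?
#' @param weighting `"equal"` (default) weights shells equally in the
#'   objective; `"ndir"` weights by the number of directions per shell.
#' @param grid_size,refine_tol Optimizer settings; see [fit_voxel()].
#' @return Object of class `"mcsmt"` with components `maps` (named list of
#'   3-D arrays: `v_int`, `lambda`, `lambda_perp_ext`, `lambda_mean_ext`,
#'   `rss`, `boundary`, `iterations`), `shell_means`, `lambda_free`, `sigma`,
#'   `mask`, `affine`, `n_failed`, and `call`. Standard methods
#'   (`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`) are available.
#' @examples
#' sim <- simulate_dataset(dim = c(3, 3, 1), v_int = 0.6, lambda = 2,
#'                         b = c(1000, 2000, 3000), n_dir = 30, snr = Inf,
#'                         seed = 1)
#' fit <- mcsmt(sim)
#' summary(fit)
#' @export
mcsmt <- function(dataset, lambda_free = lambda_free_default(), sigma = NULL,
                  bias_correct = TRUE, weighting = c("equal", "ndir"),
                  grid_size = 21, refine_tol = 1e-10) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  weighting <- match.arg(weighting)
  cl <- match.call()
  if (!dataset$normalized) dataset <- normalize_signal(dataset)
  if (bias_correct) {
    sigma <- estimate_noise_sigma(dataset, sigma)
  } else sigma <- 0
  sm <- shell_means(dataset, sigma = sigma)
  fit <- fit_shell_means(sm, lambda_free = lambda_free, weighting = weighting,
                         grid_size = grid_size, refine_tol = refine_tol)
  fit$affine <- dataset$affine
  fit$voxel_size <- dataset$voxel_size
  fit$call <- cl
  fit
}

#' Fit the microscopic model to precomputed shell means
#'
#' Volume-level driver behind [mcsmt()]; useful when the shell means come
#' from a source other than [shell_means()] (e.g. a simulation study).
#'
#' @param sm A `"shell_means"` object.
#' @inheritParams mcsmt
#' @return An `"mcsmt"` object (see [mcsmt()]).
#' @export
fit_shell_means <- function(sm, lambda_free = lambda_free_default(),
                            weighting = c("equal", "ndir"),
                            grid_size = 21, refine_tol = 1e-10) {
  stopifnot(inherits(sm, "shell_means"))
  weighting <- match.arg(weighting)
  weights <- if (weighting == "ndir") sm$n_dir / mean(sm$n_dir) else NULL
  shp <- sm$dim
  nvox <- prod(shp)
  mk_map <- function() array(NA_real_, shp)
  maps <- list(v_int = mk_map(), lambda = mk_map(), lambda_perp_ext = mk_map(),
               lambda_mean_ext = mk_map(), rss = mk_map(),
               boundary = array(NA, shp), iterations = mk_map())
  idx <- which(as.vector(sm$mask))
  n_failed <- 0L
  for (i in idx) {
    res <- tryCatch(
      fit_voxel(sm$b, sm$means[i, ], lambda_free = lambda_free,
                weights = weights, grid_size = grid_size,
                refine_tol = refine_tol),
      error = function(e) e)
    if (inherits(res, "error") || isTRUE(res$skipped)) {
      n_failed <- n_failed + inherits(res, "error")
      next
    }
    p <- res$params
    maps$v_int[i] <- p$v_int
    maps$lambda[i] <- p$lambda
    maps$lambda_perp_ext[i] <- p$lambda_perp_ext
    maps$lambda_mean_ext[i] <- p$lambda_mean_ext
    maps$rss[i] <- res$rss
    maps$boundary[i] <- any(res$boundary)
    maps$iterations[i] <- res$iterations
  }
  structure(list(maps = maps, shell_means = sm, lambda_free = lambda_free,
                 sigma = sm$sigma, mask = sm$mask, n_failed = n_failed,
                 affine = NULL, voxel_size = NULL, call = sys.call(-1)),
            class = "mcsmt")
}

#' @export
print.mcsmt <- function(x, ...) {
  cat("Multi-compartment SMT fit\n")
  cat(sprintf("  %d voxels fitted (%d failed), shells at b = %s s/mm2\n",
              sum(!is.na(x$maps$v_int)), x$n_failed,
              paste(round(x$shell_means$b * 1000), collapse = ", ")))
  cat(sprintf("  lambda_free = %.2f um^2/ms, sigma = %.4g\n",
              x$lambda_free, x$sigma))
  invisible(x)
}

#' @describeIn mcsmt Median and quartiles of the fitted parameter maps.
#' @param object,x An `"mcsmt"` object.
#' @param ... Unused.
#' @export
summary.mcsmt <- function(object, ...) {
  cf <- coef(object)
  qs <- t(apply(cf, 2, stats::quantile, c(0.25, 0.5, 0.75), na.rm = TRUE))
  colnames(qs) <- c("q1", "median", "q3")
  out <- list(quartiles = qs, n = nrow(cf), n_failed = object$n_failed,
              n_boundary = sum(object$maps$boundary, na.rm = TRUE),
              shells_b = object$shell_means$b, sigma = object$sigma,
              lambda_free = object$lambda_free)
  class(out) <- "summary.mcsmt"
  out
}

#' @export
print.summary.mcsmt <- function(x, ...) {
  cat(sprintf("Multi-compartment SMT fit: %d voxels (%d failed, %d at a bound)\n",
              x$n, x$n_failed, x$n_boundary))
  cat(sprintf("Shells: b = %s s/mm2; lambda_free = %.2f um^2/ms; sigma = %.4g\n",
              paste(round(x$shells_b * 1000), collapse = ", "),
              x$lambda_free, x$sigma))
  cat("Parameter quartiles over the mask:\n")
  print(round(x$quartiles, 4))
  invisible(x)
}

#' @export
coef.mcsmt <- function(object, ...) {
  idx <- which(as.vector(object$mask) & !is.na(as.vector(object$maps$v_int)))
  cf <- cbind(v_int = as.vector(object$maps$v_int)[idx],
              lambda = as.vector(object$maps$lambda)[idx],
              lambda_perp_ext = as.vector(object$maps$lambda_perp_ext)[idx],
              lambda_mean_ext = as.vector(object$maps$lambda_mean_ext)[idx])
  rownames(cf) <- idx
  cf
}

#' @export
predict.mcsmt <- function(object, b = NULL, b_unit = c("ms/um2", "s/mm2"), ...) {
  b_unit <- match.arg(b_unit)
  if (is.null(b)) b <- object$shell_means$b
  else if (b_unit == "s/mm2") b <- b / 1000
  cf <- coef(object)
  pred <- mean_total_grid(b, cf[, "v_int"], cf[, "lambda"])
  dimnames(pred) <- list(rownames(cf), paste0("b", round(b * 1000)))
  pred
}

#' @export
fitted.mcsmt <- function(object, ...) predict(object)

#' @export
residuals.mcsmt <- function(object, ...) {
  cf <- coef(object)
  obs <- object$shell_means$means[as.integer(rownames(cf)), , drop = FALSE]
  res <- obs - fitted(object)
  dimnames(res) <- dimnames(fitted(object))
  res
}

#' @export
plot.mcsmt <- function(x, parameter = "v_int", slice = NULL, ...) {
  m <- x$maps[[parameter]]
  if (is.null(m)) stop("unknown parameter map: ", parameter, call. = FALSE)
  if (is.null(slice)) slice <- ceiling(dim(m)[3] / 2)
  graphics::image(m[, , slice], asp = dim(m)[2] / dim(m)[1], axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("%s (slice %d)", parameter, slice), ...)
  invisible(x)
}

#' @export
simulate.mcsmt <- function(object, nsim = 1, seed = NULL, snr = 20, ...) {
  # Replicate noisy shell means under the fitted model: each voxel's
  # directional signal is taken at the orientation average (exact for an
  # isotropic orientation distribution), corrupted by Rician noise at the
  # given SNR and averaged per shell.
  if (!is.null(seed)) local_seed(seed)
  sm <- object$shell_means
  pred <- fitted(object)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    rep_means <- pred
    for (j in seq_along(sm$b)) {
      n <- sm$n_dir[j]
      A <- matrix(rep(pred[, j], each = n), nrow = n)
      noisy <- add_rician_noise(A, snr = snr)
      rep_means[, j] <- colMeans(noisy)
    }
    out[[s]] <- rep_means
  }
  if (nsim == 1) out[[1]] else out
}

#' Write the fitted parameter maps to NIfTI files
#'
#' @param fit An `"mcsmt"` object.
#' @param out_dir Output directory.
#' @param prefix Filename prefix.
#' @return Character vector of files written (see [save_parameter_maps()]).
#' @export
write_maps <- function(fit, out_dir, prefix = "smt") {
  stopifnot(inherits(fit, "mcsmt"))
  maps <- fit$maps[c("v_int", "lambda", "lambda_perp_ext", "lambda_mean_ext")]
  maps$rss <- fit$maps$rss
  maps$boundary <- fit$maps$boundary + 0
  save_parameter_maps(maps, out_dir, affine = fit$affine, mask = fit$mask,
                      prefix = prefix)
}
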