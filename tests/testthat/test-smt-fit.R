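# Stage-1 estimator: noise level, Rician adjustment, shell means, and the
# constrained least-squares fit

test_that("noise sigma is recovered from repeated b0 frames", {
  set.seed(11)
  n_b0 <- 18; sigma <- 0.02
  sch <- gradient_scheme(c(rep(0, n_b0), rep(1000, 6)),
                         rbind(matrix(0, n_b0, 3), diag(3), -diag(3)))
  nvox <- 500
  raw <- add_rician_noise(matrix(1, nvox, n_b0 + 6), snr = 1 / sigma)
  ds <- dwi_dataset(array(raw * 800, c(nvox, 1, 1, n_b0 + 6)), sch)
  est <- estimate_noise_sigma(normalize_signal(ds))
  expect_lt(abs(est / sigma - 1), 0.1)

  # noiseless frames give sigma ~ 0; user-supplied sigma bypasses estimation
  ds0 <- dwi_dataset(array(800, c(4, 1, 1, n_b0 + 6)), sch)
  expect_lt(estimate_noise_sigma(normalize_signal(ds0)), 1e-12)
  expect_equal(estimate_noise_sigma(ds0, sigma = 0.05), 0.05)

  sch1 <- gradient_scheme(c(0, 1000), rbind(0, c(1, 0, 0)))
  ds1 <- dwi_dataset(array(1, c(2, 1, 1, 2)), sch1)
  expect_error(estimate_noise_sigma(normalize_signal(ds1)), "two b = 0")
})

test_that("Rician bias adjustment satisfies the moment identities", {
  expect_equal(correct_rician_bias(0.1, 0), 0.1)
  set.seed(12)
  # pure noise: the clamp at zero leaves a small positive remainder, well
  # below the raw Rayleigh mean of sigma * sqrt(pi/2)
  m0 <- add_rician_noise(rep(0, 1e5), snr = 20)
  adj0 <- mean(correct_rician_bias(m0, 0.05))
  expect_lt(adj0, 0.5 * 0.05)
  expect_lt(adj0, mean(m0) / 2)
  # E[m^2] = A^2 + 2 sigma^2: adjusted signal recovers A within 1%
  m <- add_rician_noise(rep(0.5, 1e5), snr = 20)
  expect_lt(abs(mean(correct_rician_bias(m, 0.05)) / 0.5 - 1), 0.01)
})

test_that("shell means average per shell and respect symmetry", {
  sch <- hcp_scheme(30)
  p <- micro_params(0.6, 2)
  iso <- watson_mixture(1, matrix(c(0, 0, 1), 1), 0)
  sig <- synthesize_signals(iso, p, sch)      # isotropic: every direction equal
  ds <- dwi_dataset(array(rep(sig, each = 4), c(2, 2, 1, length(sig))), sch,
                    normalized = TRUE)
  sm <- shell_means(ds)
  expect_equal(sm$b, c(1, 2, 3))
  expect_equal(sm$n_dir, rep(30L, 3))
  expect_equal(unname(sm$means[1, ]), mean_total(c(1, 2, 3), p), tolerance = 1e-12)

  # permuting the measurement order leaves the means unchanged
  set.seed(3)
  perm <- sample(length(sig))
  sch_p <- gradient_scheme(sch$bvalues[perm], sch$directions[perm, ],
                           b_unit = "ms/um2")
  ds_p <- dwi_dataset(array(rep(sig[perm], each = 4), c(2, 2, 1, length(sig))),
                      sch_p, normalized = TRUE)
  expect_equal(shell_means(ds_p)$means, sm$means)
})

test_that("noiseless shell means are recovered exactly on an interior grid", {
  b <- c(1, 2, 3)
  for (v in seq(0.1, 0.9, length.out = 5)) {
    for (lam in seq(0.4, 2.8, length.out = 5)) {
      fit <- fit_voxel(b, mean_total(b, micro_params(v, lam)))
      expect_lt(abs(fit$params$v_int - v), 1e-4)
      expect_lt(abs(fit$params$lambda - lam), 1e-4)
      expect_false(any(fit$boundary))
    }
  }
})

test_that("degenerate inputs hit the documented limits", {
  lf <- lambda_free_default()
  free <- fit_voxel(c(1, 2), exp(-c(1, 2) * lf))
  expect_equal(free$params$v_int, 0, tolerance = 1e-6)
  expect_equal(free$params$lambda, lf, tolerance = 1e-5)
  expect_true(free$boundary[["lambda_hi"]])

  flat <- fit_voxel(c(1, 2), c(1, 1))
  expect_equal(flat$params$lambda, 0, tolerance = 1e-6)
  expect_true(flat$boundary[["lambda_lo"]])

  expect_error(fit_voxel(1, 0.5), "two or more")
  expect_error(fit_voxel(c(2, 2), c(0.5, 0.5)), "two or more")
  expect_true(fit_voxel(c(1, 2), c(NA, NA))$skipped)
  expect_error(fit_voxel(c(1, 2), c(0.5, Inf)), "non-finite")
})

test_that("the voxel fit is deterministic and refinement never loses to the grid", {
  set.seed(21)
  b <- c(1, 2, 3)
  for (i in 1:10) {
    eb <- mean_total(b, micro_params(runif(1), runif(1, 0, 3))) + rnorm(3, 0, 0.02)
    f1 <- fit_voxel(b, eb); f2 <- fit_voxel(b, eb)
    expect_identical(f1$params$v_int, f2$params$v_int)
    expect_identical(f1$rss, f2$rss)
    # grid-only objective at the best lattice point bounds the refined rss
    vs <- seq(0, 1, length.out = 21); ls <- seq(0, 3.05, length.out = 21)
    grid_best <- min(outer(seq_along(vs), seq_along(ls), Vectorize(function(i, j)
      sum((mean_total(b, micro_params(vs[i], ls[j])) - eb)^2))))
    expect_lte(f1$rss, grid_best + 1e-15)
  }
})

test_that("volume fits recover a piecewise phantom and honour the mask", {
  sch <- hcp_scheme(30)
  vmap <- array(rep(c(0.3, 0.8), each = 8), c(4, 4, 1))
  lmap <- array(rep(c(2.2, 1.2), each = 8), c(4, 4, 1))
  iso <- watson_mixture(1, matrix(c(0, 0, 1), 1), 0)
  nvox <- 16
  sig <- matrix(0, nvox, length(sch$bvalues))
  for (i in 1:nvox) {
    p <- micro_params(vmap[i], lmap[i])
    sig[i, ] <- synthesize_signals(iso, p, sch)
  }
  mask <- array(TRUE, c(4, 4, 1)); mask[4, 4, 1] <- FALSE
  ds <- dwi_dataset(array(sig, c(4, 4, 1, ncol(sig))), sch, mask = mask,
                    normalized = TRUE)
  fit <- fit_shell_means(shell_means(ds))
  expect_equal(fit$maps$v_int[mask], vmap[mask], tolerance = 1e-5)
  expect_equal(fit$maps$lambda[mask], lmap[mask], tolerance = 1e-5)
  expect_true(is.na(fit$maps$v_int[4, 4, 1]))
  # re-running is bit-identical
  fit2 <- fit_shell_means(shell_means(ds))
  expect_identical(fit$maps$v_int, fit2$maps$v_int)
})

test_that("the mcsmt object supports the standard model-methods contract", {
  sim <- simulate_dataset(dim = c(3, 3, 1), v_int = 0.6, lambda = 2,
                          n_dir = 20, snr = 50, n_b0 = 6, seed = 8)
  fit <- mcsmt(sim)
  cf <- coef(fit)
  expect_equal(colnames(cf),
               c("v_int", "lambda", "lambda_perp_ext", "lambda_mean_ext"))
  expect_equal(nrow(cf), 9)
  pr <- predict(fit)
  expect_equal(dim(pr), c(9, 3))
  expect_equal(residuals(fit), fit$shell_means$means[as.integer(rownames(cf)), ] - pr,
               ignore_attr = TRUE)
  expect_true(all(abs(residuals(fit)) < 0.05))
  s <- summary(fit)
  expect_s3_class(s, "summary.mcsmt")
  expect_output(print(s), "quartiles")
  expect_output(print(fit), "shells at b = 1000, 2000, 3000")
  # simulate() replicates are reproducible given a seed
  r1 <- simulate(fit, seed = 5, snr = 20)
  r2 <- simulate(fit, seed = 5, snr = 20)
  expect_identical(r1, r2)
  expect_equal(dim(r1), dim(pr))
  # tortuosity consistency in the maps
  expect_equal(cf[, "lambda_perp_ext"], (1 - cf[, "v_int"]) * cf[, "lambda"],
               ignore_attr = TRUE)
})
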