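# Spherical deconvolution and orientation dispersion entropy

test_that("kernel rotational harmonics reduce to the spherical mean at order 0", {
  p <- micro_params(0.6, 2)
  C <- kernel_rotational_harmonics(p, c(1, 2, 3), 8)
  expect_equal(C[, 1], 4 * pi * mean_total(c(1, 2, 3), p), tolerance = 1e-10)
  # isotropic kernel: no anisotropic orders
  iso <- micro_params(0, 2)
  Ci <- kernel_rotational_harmonics(iso, 2, 8)
  expect_lt(max(abs(Ci[, -1])), 1e-12)
  # stick-dominated kernel has an oblate profile: negative order 2
  stick <- micro_params(1, 2)
  Cs <- kernel_rotational_harmonics(stick, 3, 8)
  expect_lt(Cs[, 3], 0)
  expect_error(kernel_rotational_harmonics(p, 1, 7), "even")
})

test_that("a single-Watson voxel deconvolves to the true axis", {
  p <- micro_params(0.7, 2)
  axis <- c(0.3, -0.5, 0.81); axis <- axis / sqrt(sum(axis^2))
  sch <- uniform_sphere_scheme(90, c(1000, 3000), seed = 42)
  sig <- synthesize_signals(watson_mixture(1, matrix(axis, 1), 20), p, sch)
  fod <- deconvolve_fod(sig, sch, p)
  expect_equal(fod$lmax, 8)
  pk <- fod_peak(fod)
  ang <- acos(min(abs(sum(pk * axis)), 1)) * 180 / pi
  expect_lt(ang, 5)
  # contract: non-negative, unit mass, antipodally symmetric by construction
  expect_gte(min(fod$values), -1e-8)
  expect_equal(sum(fod$grid$weights * fod$values), 1, tolerance = 1e-6)
  expect_true(all(attr(sh_basis(matrix(c(0, 0, 1), 1), fod$lmax), "l") %% 2 == 0))
})

test_that("orthogonal equal-weight crossings split the FOD mass evenly", {
  p <- micro_params(0.7, 2)
  a1 <- c(1, 0, 0); a2 <- c(0, 1, 0)
  mix <- watson_mixture(c(0.5, 0.5), rbind(a1, a2), c(40, 40))
  sch <- uniform_sphere_scheme(90, c(1000, 3000), seed = 42)
  fod <- deconvolve_fod(synthesize_signals(mix, p, sch), sch, p)
  # partition the sphere by nearest axis (antipodal metric)
  d1 <- abs(fod$grid$points %*% a1); d2 <- abs(fod$grid$points %*% a2)
  w1 <- sum((fod$grid$weights * fod$values)[d1 > d2])
  expect_lt(abs(w1 - 0.5) / 0.5, 0.15)
})

test_that("an isotropic voxel yields a uniform FOD and near-zero entropy", {
  p <- micro_params(0.5, 1.5)
  sch <- uniform_sphere_scheme(45, c(1000, 3000), seed = 42)
  iso_sig <- synthesize_signals(watson_mixture(1, matrix(c(0, 0, 1), 1), 0),
                                p, sch)
  fod <- deconvolve_fod(iso_sig, sch, p)
  expect_lt(max(abs(fod$values - 1 / (4 * pi))) * 4 * pi, 0.02)
  expect_lt(orientation_dispersion_entropy(fod), 1e-3)
})

test_that("deconvolution inverts convolution for band-limited truths", {
  p <- micro_params(0.65, 2.1)
  sch <- uniform_sphere_scheme(90, c(1000, 3000), seed = 42)
  # band-limited ground truth: SH projection of a Watson density
  truth <- fod_from_density(watson_mixture(1, matrix(c(0.2, 0.4, 0.89), 1), 15),
                            lmax = 8)
  b0 <- mcsmt:::is_b0_measurement(sch)
  dirs <- sch$directions[!b0, ]
  shells <- sch$shell_id[!b0]
  bsh <- sch$shells$nominal_b[sort(unique(shells))]
  C <- kernel_rotational_harmonics(p, bsh, 8)
  Y <- sh_basis(dirs, 8)
  A <- Y * C[match(shells, sort(unique(shells))), attr(Y, "l") + 1]
  sig <- rep(1, length(sch$bvalues))
  sig[!b0] <- as.vector(A %*% truth$sh)
  fod <- deconvolve_fod(sig, sch, p)
  expect_equal(fod$sh_raw, truth$sh, tolerance = 1e-3)
  # order-0 consistency: the FOD's order-0 coefficient reproduces the shell
  # mean (up to the quadrature slack of a 90-point equal-weight design)
  for (k in seq_along(bsh)) {
    expect_equal(mean(sig[!b0][shells == sort(unique(shells))[k]]),
                 C[k, 1] * fod$sh_raw[1] / sqrt(4 * pi), tolerance = 5e-3)
  }
})

test_that("entropy behaves as a KL divergence from the uniform density", {
  uni <- fod_from_density(watson_mixture(1, matrix(c(0, 0, 1), 1), 0))
  expect_equal(orientation_dispersion_entropy(uni), 0, tolerance = 1e-10)
  # strictly increasing in concentration; matches the 1-D oracle
  H <- vapply(c(1, 5, 20, 100), function(k)
    orientation_dispersion_entropy(
      fod_from_density(watson_mixture(1, matrix(c(0, 0, 1), 1), k), lmax = 30)),
    numeric(1))
  expect_true(all(diff(H) > 0))
  expect_true(all(H >= 0))
  f10 <- fod_from_density(watson_mixture(1, matrix(c(0, 0, 1), 1), 10), lmax = 30)
  expect_equal(orientation_dispersion_entropy(f10), watson_entropy_oracle(10),
               tolerance = 1e-4)
  # rotation invariance
  f10r <- fod_from_density(watson_mixture(1, matrix(c(0.6, -0.64, 0.48), 1), 10),
                           lmax = 30)
  expect_equal(orientation_dispersion_entropy(f10r),
               orientation_dispersion_entropy(f10), tolerance = 1e-8)
  # a non-normalized FOD is rejected
  broken <- uni; broken$values <- broken$values * 2
  expect_error(orientation_dispersion_entropy(broken), "normalized")
})

test_that("volume-level FOD estimation fills SH and entropy maps", {
  sim <- simulate_dataset(dim = c(2, 2, 1), v_int = 0.7, lambda = 2,
                          b = c(1000, 3000), n_dir = 30, snr = Inf,
                          kappa = 20, seed = 9)
  ds <- normalize_signal(sim)
  fit <- mcsmt(ds, bias_correct = FALSE)
  fv <- fod_volume(ds, fit)
  expect_equal(fv$lmax, 4)     # 30 directions per shell: reduced resolution
  expect_equal(dim(fv$sh)[4], (4 + 1) * (4 + 2) / 2)
  expect_true(all(is.finite(fv$entropy)))
  expect_true(all(fv$entropy >= 0))
})
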