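# Two-compartment microscopic signal model and its closed-form spherical means

test_that("compartment signals satisfy their limiting cases", {
  expect_equal(stick_signal(1, 1, 2), exp(-2))
  expect_equal(stick_signal(5, 0, 2), 1)   # perpendicular stick: no attenuation
  expect_equal(stick_signal(0, 0.7, 2), 1)
  expect_equal(stick_signal(1, -0.3, 2), stick_signal(1, 0.3, 2))

  # zeppelin reduces to stick at lambda_perp = 0, to isotropic at = lambda
  t <- seq(-1, 1, by = 0.25)
  expect_equal(zeppelin_signal(2, t, 1.7, 0), stick_signal(2, t, 1.7))
  expect_equal(zeppelin_signal(2, t, 1.7, 1.7), rep(exp(-2 * 1.7), length(t)))
  expect_equal(zeppelin_signal(2, 0.5, 2, 0.8),
               exp(-2 * 0.25 * 2) * exp(-2 * 0.75 * 0.8))

  # volume-fraction boundaries
  p1 <- micro_params(1, 2)
  expect_equal(compartment_signal(3, t, p1), stick_signal(3, t, 2))
  p0 <- micro_params(0, 2)   # tortuosity gives lambda_perp = lambda: isotropic
  expect_equal(compartment_signal(3, t, p0), rep(exp(-3 * 2), length(t)))
  # at t = 1 both compartments coincide
  p5 <- micro_params(0.5, 2)
  expect_equal(compartment_signal(1, 1, p5), exp(-2))
})

test_that("signal preconditions are enforced", {
  expect_error(stick_signal(1, 1.1, 2), "t")
  expect_error(zeppelin_signal(1, 0, 1, 1.5), "lambda_perp")
  expect_error(mean_stick(-1, 2), "non-negative")
  expect_error(micro_params(1.2, 1), "v_int")
  expect_error(micro_params(0.5, 3.5), "lambda_free")
})

test_that("tortuosity and extra-neurite mean diffusivity follow the model", {
  expect_equal(tortuosity_transverse(0.5, 2), 1)
  expect_equal(tortuosity_transverse(1, 2), 0)
  expect_equal(tortuosity_transverse(0, 2), 2)
  expect_equal(extraneurite_mean_diffusivity(0, 2), 2)
  expect_equal(extraneurite_mean_diffusivity(1, 2), 2 / 3)
  # (lambda_par + 2 lambda_perp)/3 identity for random parameters
  set.seed(4)
  v <- runif(20); lam <- runif(20, 0, 3)
  expect_equal(extraneurite_mean_diffusivity(v, lam),
               (lam + 2 * tortuosity_transverse(v, lam)) / 3)
})

test_that("closed-form spherical means match frozen quadrature values", {
  # independent Gauss-Legendre quadrature values, frozen
  expect_equal(mean_stick(1, 2), 0.5981440, tolerance = 1e-6)
  expect_equal(mean_stick(3, 3), sqrt(pi) * (2 * pnorm(3 * sqrt(2)) - 1) / 6,
               tolerance = 1e-12)
  expect_equal(mean_stick(3, 3), 0.2954024, tolerance = 1e-6)
  expect_equal(mean_zeppelin(2, 2, 0.8), 0.1122093, tolerance = 1e-6)
  expect_equal(mean_stick(1e-9, 1), 1, tolerance = 1e-8)
  expect_equal(mean_zeppelin(2, 1.5, 1.5), exp(-3))
  expect_equal(mean_zeppelin(2, 1.5, 0), mean_stick(2, 1.5))
})

test_that("closed forms agree with the quadrature oracle over a parameter grid", {
  for (b in c(0.1, 0.7, 2, 4, 6)) for (lam in c(0.1, 1, 2, 3)) {
    expect_equal(mean_stick(b, lam),
                 spherical_mean_oracle(function(u) stick_signal(b, u, lam)),
                 tolerance = 1e-10)
    for (lp in c(0, 0.4 * lam, lam)) {
      expect_equal(mean_zeppelin(b, lam, lp),
                   spherical_mean_oracle(function(u) zeppelin_signal(b, u, lam, lp)),
                   tolerance = 1e-10)
    }
  }
  p <- micro_params(0.6, 2)
  expect_equal(mean_total(1, p),
               spherical_mean_oracle(function(u) compartment_signal(1, u, p)),
               tolerance = 1e-10)
  expect_equal(mean_total(0, p), 1)
})

test_that("series switch-over is continuous and means stay in bounds", {
  eps <- 1e-10
  jump <- abs(mean_stick(1, 1e-6 + eps) - mean_stick(1, 1e-6 - eps))
  expect_lt(jump / mean_stick(1, 1e-6), 1e-9)
  b <- seq(0.05, 6, length.out = 40)
  p <- micro_params(0.4, 1.8)
  m <- mean_total(b, p)
  expect_true(all(diff(m) < 0))          # strictly decreasing in b
  expect_true(all(m > 0 & m <= 1))
  # decreasing in lambda at fixed b
  lams <- seq(0.1, 3, length.out = 20)
  mt <- vapply(lams, function(l) mean_total(2, micro_params(0.4, l)), 0)
  expect_true(all(diff(mt) < 0))
  # exp(-b lambda) <= mean_zeppelin <= 1
  mz <- mean_zeppelin(b, 2, 0.7)
  expect_true(all(mz >= exp(-b * 2) - 1e-12 & mz <= 1))
})

test_that("free-water voxel attenuates as exp(-b lambda_free)", {
  csf <- micro_params(0, lambda_free_default(), lambda_free_default())
  expect_equal(mean_total(1, csf), exp(-3.05), tolerance = 1e-12)
  expect_equal(exp(-3.05), 0.04735892, tolerance = 1e-7)
  expect_equal(lambda_free_default("exvivo"), 1.88)
})

test_that("spherical mean is invariant to the orientation distribution", {
  # the core theorem: direction-averaged convolved signal equals the
  # closed-form mean for any Watson-mixture FOD
  des <- dense_design(c(1, 3))
  p <- micro_params(0.7, 2.2)
  for (s in 1:5) {
    mix <- sample_dpm_fod(seed = 100 + s)
    sig <- synthesize_signals(mix, p, des$scheme)
    expect_equal(dense_shell_means(des, sig), mean_total(c(1, 3), p),
                 tolerance = 1e-9)
  }
})
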