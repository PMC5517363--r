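# Gradient tables, shell detection, normalization and NIfTI round trips

# b0 rows by zero direction
is_b0_zero <- function(sch) rowSums(sch$directions^2) < 0.5

test_that("gradient schemes preserve counts and unit conventions", {
  set.seed(2)
  dirs <- matrix(rnorm(288 * 3), ncol = 3)
  bv <- rep(c(5, 1000, 2000, 3000), each = 72)
  sch <- gradient_scheme(bv, dirs)
  expect_length(sch$bvalues, 288)
  expect_equal(sch$bvalues[100], 1)            # s/mm2 -> ms/um2
  nrm <- sqrt(rowSums(sch$directions^2))
  expect_true(all(abs(nrm[!is_b0_zero(sch)] - 1) < 1e-6))

  # zero vector at small b is accepted and lands in the b0 shell
  sch2 <- gradient_scheme(c(5, 1000), rbind(c(0, 0, 0), c(1, 1, 0)))
  expect_true(sch2$shells$is_b0[sch2$shell_id[1]])

  expect_error(gradient_scheme(rep(0, 287), dirs), "287")
  expect_error(gradient_scheme(c(NA, 1000), diag(3)[1:2, ]), "non-finite")
})

test_that("shell detection clusters b-values and flags ambiguity", {
  res <- detect_shells(c(5, 995, 1005, 2000, 2005) / 1000)
  expect_equal(res$shells$nominal_b, c(0, 1, 2))
  expect_equal(res$shells$is_b0, c(TRUE, FALSE, FALSE))

  bv <- rep(c(0, 1, 2, 3), each = 90)
  res2 <- detect_shells(bv)
  expect_equal(res2$shells$n[!res2$shells$is_b0], rep(90L, 3))

  expect_error(detect_shells(c(0, 1, 1.5), tolerance_b = 0.6), "ambiguous")

  # permutation invariance of the assignment
  set.seed(9)
  perm <- sample(length(bv))
  res3 <- detect_shells(bv[perm])
  expect_equal(res3$shells, res2$shells)
  expect_equal(bv[perm][res3$shell_id == 2], bv[res2$shell_id == 2])
})

test_that("normalization divides by the voxel b0 mean and masks degenerates", {
  sch <- gradient_scheme(c(0, 0, 0, 1000), rbind(0, 0, 0, c(1, 0, 0)))
  sig <- array(0, c(2, 1, 1, 4))
  sig[1, 1, 1, ] <- c(100, 102, 98, 60)
  sig[2, 1, 1, ] <- 0                       # all-zero voxel
  ds <- normalize_signal(dwi_dataset(sig, sch))
  expect_equal(ds$signal[1, 1, 1, 4], 0.6)
  expect_false(ds$mask[2, 1, 1])
  expect_true(ds$mask[1, 1, 1])
  # idempotence: renormalizing changes nothing
  ds2 <- normalize_signal(ds)
  expect_equal(ds2$signal[1, 1, 1, ], ds$signal[1, 1, 1, ])

  sch_nob0 <- gradient_scheme(c(1000, 2000), rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_error(normalize_signal(dwi_dataset(array(1, c(1, 1, 1, 2)), sch_nob0)),
               "b = 0")
})

test_that("noiseless free-water voxel normalizes to exp(-b lambda_free)", {
  des <- dense_design(1, n_theta = 8)
  csf <- micro_params(0, 3.05, 3.05)
  mix <- watson_mixture(1, matrix(c(0, 0, 1), 1), 0)
  s <- synthesize_signals(mix, csf, des$scheme)
  expect_equal(unique(round(s, 10)), round(exp(-3.05), 10))
})

test_that("datasets load from NIfTI with FSL tables and report mismatches", {
  ds <- simulate_dataset(dim = c(3, 2, 2), n_dir = 12, snr = Inf, seed = 3)
  paths <- write_dataset_files(ds)
  got <- load_dwi(paths$dwi, paths$bval, paths$bvec)
  expect_length(got$scheme$bvalues, length(ds$scheme$bvalues))
  expect_equal(dim(got$signal), dim(ds$signal))
  expect_equal(got$scheme$shells$nominal_b, ds$scheme$shells$nominal_b)
  expect_true(all(got$mask))

  # truncated bval file: count mismatch names the offending file
  bad <- file.path(paths$dir, "short.bval")
  writeLines(paste(rep(0, length(ds$scheme$bvalues) - 1), collapse = " "), bad)
  expect_error(read_gradient_table(bad, paths$bvec), "short.bval")
  expect_error(load_dwi(paths$dwi, paths$bval, file.path(paths$dir, "none.bvec")),
               "not found")
})

test_that("parameter maps round-trip through float32 NIfTI with NaN masking", {
  set.seed(6)
  maps <- list(v_int = array(runif(12), c(3, 2, 2)),
               lambda = array(runif(12, 0, 3), c(3, 2, 2)))
  mask <- array(TRUE, c(3, 2, 2)); mask[1, 1, 1] <- FALSE
  out <- tempfile("maps")
  paths <- save_parameter_maps(maps, out, mask = mask,
                               affine = diag(c(2, 2, 2, 1)))
  expect_named(paths, c("v_int", "lambda"))
  back <- RNifti::readNifti(paths[["v_int"]])
  expect_true(is.nan(as.array(back)[1, 1, 1]))
  inmask <- as.vector(back)[as.vector(mask)]
  expect_equal(inmask, as.vector(maps$v_int)[as.vector(mask)],
               tolerance = 1e-7)   # float32 quantization only
  expect_equal(unname(RNifti::xform(back)[1, 1]), 2)
  # bit-exact at float32: a second round trip is the identity
  maps2 <- list(v_int = as.array(back))
  paths2 <- save_parameter_maps(maps2, tempfile("maps2"))
  expect_identical(as.vector(RNifti::readNifti(paths2[["v_int"]])),
                   as.vector(back))
})
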