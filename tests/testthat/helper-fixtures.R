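# shared fixtures built in code

# HCP-style three-shell scheme used across tests (cached inside the package)
hcp_scheme <- function(n_dir = 90) {
  uniform_sphere_scheme(n_dir, c(1000, 2000, 3000), seed = 42)
}

# write a dataset to NIfTI + FSL gradient tables in a temp dir
write_dataset_files <- function(ds, dir = tempfile("dwi")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(dwi = file.path(dir, "dwi.nii.gz"),
                bval = file.path(dir, "dwi.bval"),
                bvec = file.path(dir, "dwi.bvec"),
                dir = dir)
  RNifti::writeNifti(RNifti::asNifti(ds$signal), paths$dwi)
  write_gradient_table(ds$scheme, paths$bval, paths$bvec)
  paths
}

# quadrature-weighted dense design: every point of a sphere_grid at each shell
dense_design <- function(b_ms_um2 = c(1, 2, 3), n_theta = 24) {
  g <- sphere_grid(n_theta)
  n <- nrow(g$points)
  scheme <- gradient_scheme(rep(b_ms_um2 * 1000, each = n),
                            do.call(rbind, rep(list(g$points), length(b_ms_um2))))
  list(scheme = scheme, grid = g, b = b_ms_um2)
}

# weighted per-shell spherical mean of signals on a dense design
dense_shell_means <- function(design, signals) {
  vapply(seq_along(design$b), function(k) {
    idx <- which(design$scheme$shell_id == k)
    sum(design$grid$weights * signals[idx]) / (4 * pi)
  }, numeric(1))
}
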