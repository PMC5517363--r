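#' Diffusion-weighted dataset
#'
#' Bundles a 4-D signal array (x, y, z, measurement) with its gradient scheme,
#' a brain mask and voxel geometry.
#'
#' @param signal 4-D numeric array; the 4th axis indexes measurements.
#' @param scheme A [gradient_scheme()] whose length matches `dim(signal)[4]`.
#' @param mask Logical 3-D array of voxels to process; default all `TRUE`.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param affine Optional 4 x 4 voxel-to-world matrix (carried through to any
#'   maps written as NIfTI).
#' @param normalized Logical; `TRUE` once the signal has been divided by the
#'   voxel-wise mean b = 0 signal.
#' @return Object of class `"dwi_dataset"`.
#' @export
dwi_dataset <- function(signal, scheme, mask = NULL, voxel_size = c(1, 1, 1),
                        affine = NULL, normalized = FALSE) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- dim(signal)
  if (length(d) != 4L)
    stop("'signal' must be a 4-D array", call. = FALSE)
  if (d[4] != length(scheme$bvalues))
    stop("signal has ", d[4], " measurements but the gradient scheme has ",
         length(scheme$bvalues), call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), d[1:3]))
    stop("mask shape does not match the spatial signal shape", call. = FALSE)
  structure(list(signal = signal, scheme = scheme, mask = mask,
                 voxel_size = voxel_size, affine = affine,
                 normalized = isTRUE(normalized)),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("Diffusion dataset: %d x %d x %d voxels, %d measurements%s\n",
              d[1], d[2], d[3], d[4],
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  mask: %d of %d voxels\n", sum(x$mask), prod(d[1:3])))
  print(x$scheme)
  invisible(x)
}

#' Load a diffusion-weighted dataset from disk
#'
#' Reads a NIfTI-1 volume together with FSL-style `bval`/`bvec` gradient
#' tables and an optional brain mask. Directions are renormalized to unit
#' length, b-values converted to ms/micrometre^2 and shells detected.
#'
#' @param image_path Path to the 4-D NIfTI volume.
#' @param bval_path,bvec_path FSL gradient table files.
#' @param mask_path Optional NIfTI mask (nonzero = included); all-true if
#'   absent.
#' @param tolerance_b Shell clustering tolerance, ms/micrometre^2.
#' @return A [dwi_dataset()].
#' @export
load_dwi <- function(image_path, bval_path, bvec_path, mask_path = NULL,
                     tolerance_b = 0.05) {
  if (!file.exists(image_path)) stop("file not found: ", image_path, call. = FALSE)
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  scheme <- read_gradient_table(bval_path, bvec_path, tolerance_b)
  if (dim(arr)[4] != length(scheme$bvalues))
    stop("image '", image_path, "' has ", dim(arr)[4],
         " frames but the gradient table has ", length(scheme$bvalues),
         " entries", call. = FALSE)
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop("file not found: ", mask_path, call. = FALSE)
    mask <- as.array(RNifti::readNifti(mask_path)) != 0
  }
  pd <- RNifti::pixdim(img)
  dwi_dataset(arr, scheme, mask = mask,
              voxel_size = pd[seq_len(min(3, length(pd)))],
              affine = structure(RNifti::xform(img), code = NULL))
}

#' Normalize the diffusion signal by the b = 0 signal
#'
#' Divides every voxel's signal by that voxel's mean b = 0 signal, yielding
#' dimensionless attenuations. Voxels whose mean b = 0 signal is not positive
#' are removed from the mask. Idempotent in the sense that renormalizing a
#' normalized dataset divides by a b0 mean of (approximately) one.
#'
#' @param dataset A [dwi_dataset()].
#' @return The dataset with normalized signal and updated mask.
#' @export
normalize_signal <- function(dataset) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  b0 <- is_b0_measurement(dataset$scheme)
  if (!any(b0))
    stop("normalization requires at least one b = 0 measurement", call. = FALSE)
  d <- dim(dataset$signal)
  mat <- matrix(dataset$signal, prod(d[1:3]), d[4])
  b0mean <- rowMeans(mat[, b0, drop = FALSE])
  ok <- is.finite(b0mean) & b0mean > 0
  mat <- mat / b0mean  # recycling by row via division of matrix by vector
  mat[!ok, ] <- NA_real_
  dataset$signal <- array(mat, d)
  dataset$mask <- dataset$mask & array(ok, d[1:3])
  dataset$normalized <- TRUE
  dataset
}

#' Write parameter maps as NIfTI files
#'
#' Writes one float32 NIfTI-1 file per map, preserving the input affine.
#' Out-of-mask voxels are written as NaN.
#'
#' @param maps Named list of 3-D numeric arrays sharing one spatial shape.
#' @param out_dir Output directory (created if needed).
#' @param affine Optional 4 x 4 voxel-to-world matrix.
#' @param mask Optional logical array; voxels outside it become NaN.
#' @param prefix Filename prefix (default `"smt"`).
#' @return Character vector of the files written, named by map.
#' @export
save_parameter_maps <- function(maps, out_dir, affine = NULL, mask = NULL,
                                prefix = "smt") {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  shp <- dim(maps[[1]])
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!identical(dim(m), shp))
      stop("map '", nm, "' has a different spatial shape", call. = FALSE)
    if (!is.null(mask)) m[!mask] <- NaN
    img <- if (is.null(affine)) RNifti::asNifti(m, datatype = "float")
    else {
      # carry the affine through the sform, which stores it as explicit rows
      hdr <- RNifti::niftiHeader(m)
      hdr$sform_code <- 2L; hdr$qform_code <- 0L
      hdr$srow_x <- affine[1, ]; hdr$srow_y <- affine[2, ]
      hdr$srow_z <- affine[3, ]
      hdr$pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)), 1, 1, 1, 1)
      RNifti::asNifti(m, reference = hdr, datatype = "float")
    }
    path <- file.path(out_dir, paste0(prefix, "_", nm, ".nii.gz"))
    RNifti::writeNifti(img, path)
    paths[nm] <- path
  }
  paths
}
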