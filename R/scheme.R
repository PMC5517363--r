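#' Gradient scheme
#'
#' Per-measurement diffusion weighting and gradient direction, with b-shell
#' grouping. b-values are stored internally in ms/micrometre^2 (input
#' s/mm^2 divided by 1000) so that `b * lambda` is dimensionless; directions
#' are renormalized to unit length (the zero vector is kept for b~0 frames).
#' Directions are interpreted in the image coordinate frame (FSL bvec
#' convention) and antipodal pairs `g`, `-g` are regarded as equivalent.
#'
#' @param bvalues Numeric vector of b-values.
#' @param directions N x 3 matrix of gradient directions (rows).
#' @param b_unit Unit of `bvalues`: `"s/mm2"` (default, divided by 1000 on
#'   input) or `"ms/um2"` (stored as given).
#' @param tolerance_b Shell clustering tolerance in ms/micrometre^2
#'   (default 0.05, i.e. 50 s/mm^2). Measurements whose nominal shell b-value
#'   is at most the tolerance count as b = 0.
#' @return An object of class `"gradient_scheme"`: a list with `bvalues`
#'   (ms/um^2), `directions`, `shell_id` (integer per measurement),
#'   `shells` (data.frame with `nominal_b`, `n`, `is_b0`) and `tolerance_b`.
#' @examples
#' scheme <- gradient_scheme(c(0, 1000, 2000), diag(3))
#' scheme$shells
#' @export
gradient_scheme <- function(bvalues, directions, b_unit = c("s/mm2", "ms/um2"),
                            tolerance_b = 0.05) {
  b_unit <- match.arg(b_unit)
  bvalues <- as.numeric(bvalues)
  if (any(!is.finite(bvalues)))
    stop("non-finite b-value in gradient table", call. = FALSE)
  if (any(bvalues < 0)) stop("negative b-value in gradient table", call. = FALSE)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("'directions' must have 3 columns", call. = FALSE)
  if (nrow(directions) != length(bvalues))
    stop("number of directions (", nrow(directions),
         ") does not match number of b-values (", length(bvalues), ")", call. = FALSE)
  if (b_unit == "s/mm2") bvalues <- bvalues / 1000
  nrm <- sqrt(rowSums(directions^2))
  zero <- nrm < 1e-8
  directions[!zero, ] <- directions[!zero, , drop = FALSE] / nrm[!zero]
  directions[zero, ] <- 0
  sch <- detect_shells(bvalues, tolerance_b)
  structure(list(bvalues = bvalues, directions = directions,
                 shell_id = sch$shell_id, shells = sch$shells,
                 tolerance_b = tolerance_b),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", length(x$bvalues), "measurements,",
      nrow(x$shells), "shells\n")
  sh <- x$shells
  sh$nominal_b_s_mm2 <- round(sh$nominal_b * 1000)
  print(sh[, c("nominal_b_s_mm2", "n", "is_b0")], row.names = FALSE)
  invisible(x)
}

#' Group b-values into shells
#'
#' Clusters the measurement b-values into shells by one-dimensional single
#' linkage: measurements whose sorted b-values differ by at most twice the
#' tolerance are linked, so all members of a shell lie within +/- tolerance of
#' a common centre. A linked cluster spanning more than twice the tolerance is
#' ambiguous and raises an error. The nominal shell b-value is the cluster
#' mean rounded to the nearest 50 s/mm^2; a shell with nominal b at most the
#' tolerance is the b = 0 shell.
#'
#' @param bvalues Numeric vector of b-values in ms/micrometre^2.
#' @param tolerance_b Positive clustering tolerance, ms/micrometre^2.
#' @return List with `shell_id` (integer vector, one entry per measurement;
#'   shells ordered by increasing b) and `shells` (data.frame with
#'   `nominal_b`, `n`, `is_b0`).
#' @export
detect_shells <- function(bvalues, tolerance_b = 0.05) {
  if (!is.numeric(tolerance_b) || length(tolerance_b) != 1L || tolerance_b <= 0)
    stop("'tolerance_b' must be a positive scalar", call. = FALSE)
  if (any(!is.finite(bvalues))) stop("non-finite b-value", call. = FALSE)
  ord <- order(bvalues)
  bs <- bvalues[ord]
  n <- length(bs)
  cl <- integer(n)
  cl[1L] <- 1L
  if (n > 1L) for (i in 2:n)
    cl[i] <- if (bs[i] - bs[i - 1L] <= 2 * tolerance_b) cl[i - 1L] else cl[i - 1L] + 1L
  for (k in unique(cl)) {
    span <- diff(range(bs[cl == k]))
    if (span > 2 * tolerance_b)
      stop("ambiguous shell structure: b-values {",
           paste(signif(sort(unique(bs[cl == k])) * 1000, 6), collapse = ", "),
           "} s/mm2 link into one cluster spanning ", signif(span * 1000, 4),
           " s/mm2 (more than twice the tolerance)", call. = FALSE)
  }
  shell_id <- integer(n)
  shell_id[ord] <- cl
  nominal <- vapply(seq_len(max(cl)), function(k) {
    round(mean(bs[cl == k]) / 0.05) * 0.05
  }, numeric(1))
  shells <- data.frame(nominal_b = nominal,
                       n = as.integer(tabulate(cl)),
                       is_b0 = nominal <= tolerance_b)
  list(shell_id = shell_id, shells = shells)
}

# logical index of b0 measurements (shell nominal b <= tolerance, or raw
# b <= tolerance for safety)
is_b0_measurement <- function(scheme) {
  scheme$shells$is_b0[scheme$shell_id] | scheme$bvalues <= scheme$tolerance_b
}

#' Read an FSL-style gradient table
#'
#' Reads whitespace-separated `bval` (one row of scalars) and `bvec`
#' (3 rows x N columns) text files into a [gradient_scheme()].
#'
#' @param bval_path,bvec_path Paths to the FSL gradient table files.
#' @param tolerance_b Shell clustering tolerance, ms/micrometre^2.
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, tolerance_b = 0.05) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3L)
    stop("malformed bvec file '", bvec_path, "': expected 3 rows, found ",
         nrow(bvec), call. = FALSE)
  if (ncol(bvec) != length(bval))
    stop("gradient table mismatch: ", length(bval), " b-values in '", bval_path,
         "' but ", ncol(bvec), " directions in '", bvec_path, "'", call. = FALSE)
  gradient_scheme(bval, t(bvec), b_unit = "s/mm2", tolerance_b = tolerance_b)
}

#' Write an FSL-style gradient table
#'
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output file paths.
#' @return Invisibly, the scheme.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  cat(paste(round(scheme$bvalues * 1000, 6), collapse = " "), "\n",
      file = bval_path, sep = "")
  utils::write.table(t(scheme$directions), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(scheme)
}

#' Restrict a scheme (and optionally data) to selected shells
#'
#' @param scheme A [gradient_scheme()].
#' @param keep_b Nominal shell b-values to keep, in s/mm^2; the b0 shell is
#'   always kept.
#' @return Logical vector of measurements retained.
#' @export
select_shells <- function(scheme, keep_b) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  keep_b <- as.numeric(keep_b) / 1000
  keep_shell <- scheme$shells$is_b0 |
    vapply(scheme$shells$nominal_b,
           function(b) any(abs(b - keep_b) <= scheme$tolerance_b), logical(1))
  keep_shell[scheme$shell_id]
}
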