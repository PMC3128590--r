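# Acquisition schemes, gradient tables and diffusion-weighted volumes.
#
# Units follow the common convention for this kind of data: b-values in
# s/mm^2 and diffusivities in mm^2/s, so b*D is dimensionless; pulse
# timings big_delta (gradient separation) and small_delta (duration) in ms
# are carried as metadata only (the model folds time dependence into
# effective diffusivities).

#' Construct an acquisition scheme
#'
#' @param bvals numeric vector of diffusion weightings, s/mm^2
#' @param bvecs n x 3 matrix of unit gradient directions (rows with b = 0
#'   may be arbitrary unit vectors)
#' @param big_delta gradient separation, ms
#' @param small_delta gradient duration, ms
#' @param n_averages number of averaged acquisitions per measurement
#' @return an object of class `acquisition_scheme`
#' @export
acquisition_scheme <- function(bvals, bvecs, big_delta = 8, small_delta = 2,
                               n_averages = 1L) {
  bvals <- as.double(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 columns")
  if (nrow(bvecs) != length(bvals))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") disagree in measurement count")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  if (!any(bvals == 0)) stop("scheme must contain at least one b = 0 row")
  if (!(small_delta > 0) || big_delta < small_delta)
    stop("pulse timings must satisfy big_delta >= small_delta > 0")
  if (!(n_averages >= 1)) stop("n_averages must be a positive integer")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("diffusion-weighted directions must be unit vectors (|norm - 1| <= 1e-6)")
  structure(list(bvals = bvals, bvecs = bvecs,
                 big_delta = as.double(big_delta),
                 small_delta = as.double(small_delta),
                 n_averages = as.integer(n_averages)),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  shells <- sort(unique(x$bvals))
  cat("Acquisition scheme:", length(x$bvals), "measurements,",
      length(shells), "b-value shells\n")
  cat("  b =", paste(shells, collapse = ", "), "s/mm^2\n")
  cat("  Delta/delta =", x$big_delta, "/", x$small_delta, "ms;",
      x$n_averages, "average(s)\n")
  invisible(x)
}

#' @export
length.acquisition_scheme <- function(x) length(x$bvals)

#' Construct a diffusion-weighted volume
#'
#' @param signal 4-D non-negative array (x, y, z, measurement)
#' @param scheme an [acquisition_scheme()]
#' @param voxel_size voxel edge lengths, mm (length 3)
#' @return an object of class `dwi_volume`
#' @export
dwi_volume <- function(signal, scheme, voxel_size = c(1, 1, 1)) {
  if (!inherits(scheme, "acquisition_scheme"))
    stop("scheme must be an acquisition_scheme")
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4-D array (x, y, z, measurement)")
  if (dim(signal)[4L] != length(scheme))
    stop("measurement axis (", dim(signal)[4L],
         ") does not match scheme length (", length(scheme), ")")
  if (prod(dim(signal)) == 0L) stop("volume has zero voxels")
  finite <- signal[is.finite(signal)]
  if (any(finite < 0))
    stop("magnitude signal must be non-negative")
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = rep_len(as.double(voxel_size), 3L)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI volume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "measurements\n")
  cat("  voxel size:", paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

#' Read FSL-dialect gradient tables
#'
#' `.bval` is a whitespace-separated row of b-values; `.bvec` is three rows
#' (x, y, z components), one column per measurement.
#'
#' @param bval_path,bvec_path paths to the two text tables
#' @return list with `bvals` (vector) and `bvecs` (n x 3 matrix)
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = double(), quiet = TRUE)
  raw <- scan(bvec_path, what = double(), quiet = TRUE)
  if (length(raw) != 3L * length(bvals))
    stop("bvec table in ", bvec_path, " has ", length(raw),
         " entries; expected 3 x ", length(bvals))
  bvecs <- t(matrix(raw, nrow = 3L, byrow = TRUE))
  list(bvals = bvals, bvecs = bvecs)
}

#' Read a diffusion-weighted dataset
#'
#' Reads a 4-D NIfTI plus FSL-style `.bval`/`.bvec` tables. Direction rows
#' at b > 0 whose norm deviates from 1 by less than `1e-3` are
#' re-normalized; larger deviations are rejected.
#'
#' @param image_path 4-D NIfTI path
#' @param bval_path,bvec_path gradient table paths
#' @param big_delta,small_delta,n_averages scheme metadata (not stored in
#'   FSL tables)
#' @return a [dwi_volume()]
#' @export
read_dwi <- function(image_path, bval_path, bvec_path,
                     big_delta = 8, small_delta = 2, n_averages = 1L) {
  img <- read_nifti(image_path)
  if (length(dim(img$data)) != 4L)
    stop("expected a 4-D image in ", image_path)
  tab <- read_gradient_table(bval_path, bvec_path)
  if (length(tab$bvals) != dim(img$data)[4L])
    stop("gradient tables list ", length(tab$bvals),
         " measurements but image has ", dim(img$data)[4L], " frames")
  if (any(tab$bvals < 0)) stop("negative b-value in ", bval_path)
  bvecs <- tab$bvecs
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- tab$bvals > 0
  bad <- dw & abs(nrm - 1) >= 1e-3
  if (any(bad))
    stop("non-unit gradient direction(s) at b > 0 in ", bvec_path,
         " (rows ", paste(which(bad), collapse = ", "), ")")
  fix <- dw & nrm > 0
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  scheme <- acquisition_scheme(tab$bvals, bvecs, big_delta, small_delta,
                               n_averages)
  dwi_volume(img$data, scheme, voxel_size = img$pixdim)
}

#' Write a diffusion-weighted dataset
#'
#' Signal is stored as float64 NIfTI so that a read/write round trip is
#' bit-exact; gradient tables are written with enough digits to round-trip
#' to 1e-6.
#'
#' @param vol a [dwi_volume()]
#' @param image_path,bval_path,bvec_path output paths
#' @export
write_dwi <- function(vol, image_path, bval_path, bvec_path) {
  if (!inherits(vol, "dwi_volume")) stop("vol must be a dwi_volume")
  write_nifti(vol$signal, image_path, pixdim = vol$voxel_size,
              datatype = "float64")
  writeLines(paste(formatC(vol$scheme$bvals, format = "g", digits = 10),
                   collapse = " "), bval_path)
  bv <- t(vol$scheme$bvecs)
  writeLines(apply(bv, 1L, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' The packaged 54-point gradient direction set
#'
#' A deterministic near-uniform antipodally balanced set of 54 unit vectors
#' obtained by electrostatic-repulsion optimization (antipodal energy) from
#' a fixed seed, with per-vector signs chosen to null the resultant. It
#' integrates even polynomials through degree 4 to better than 1e-2
#' relative error (see [validate_design()]).
#'
#' @return 54 x 3 matrix of unit row vectors
#' @export
default_directions <- function() {
  path <- system.file("extdata", "dirs54.tsv", package = "neuritemap",
                      mustWork = TRUE)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m / sqrt(rowSums(m^2))
}

#' The default multi-shell acquisition scheme
#'
#' Nine b-value shells (0, 2000, 3000, 4000, 5000, 6000, 8000, 10000,
#' 15000 s/mm^2) with six directions each, 54 measurements total, pulse
#' timings Delta/delta = 8/2 ms and four averages — the fixed-tissue
#' high-field protocol this pipeline is designed around. Directions come
#' from [default_directions()], partitioned into nine sextets (the b = 0
#' sextet's directions are irrelevant to the signal).
#'
#' @return an [acquisition_scheme()]
#' @export
default_scheme <- function() {
  shells <- c(0, 2000, 3000, 4000, 5000, 6000, 8000, 10000, 15000)
  acquisition_scheme(bvals = rep(shells, each = 6L),
                     bvecs = default_directions(),
                     big_delta = 8, small_delta = 2, n_averages = 4L)
}

# Exact average of x^a y^b z^c over the unit sphere; zero unless all
# exponents are even.
.sphere_monomial_avg <- function(p) {
  if (any(p %% 2L == 1L)) return(0)
  2 * prod(gamma((p + 1) / 2)) / gamma((sum(p) + 3) / 2) / (4 * pi)
}

#' Quadrature quality of a direction set
#'
#' Compares the point-set average of every monomial of even total degree
#' `<= max_degree` with its exact sphere average. For monomials whose exact
#' average is nonzero the relative error is reported; for zero-average
#' monomials the absolute error. Returns the worst case per degree.
#'
#' @param directions n x 3 matrix of unit vectors (n >= 2)
#' @param max_degree highest polynomial degree checked
#' @return data.frame with columns `degree` and `worst_error`
#' @export
validate_design <- function(directions, max_degree = 4L) {
  directions <- as.matrix(directions)
  if (nrow(directions) < 2L)
    stop("need at least 2 direction vectors")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  degrees <- seq(2L, max_degree, by = 2L)
  worst <- vapply(degrees, function(d) {
    errs <- c()
    for (a in 0:d) for (b in 0:(d - a)) {
      cc <- d - a - b
      ex <- .sphere_monomial_avg(c(a, b, cc))
      pt <- mean(directions[, 1L]^a * directions[, 2L]^b * directions[, 3L]^cc)
      errs <- c(errs, if (abs(ex) > 1e-12) abs(pt - ex) / abs(ex)
                      else abs(pt - ex))
    }
    max(errs)
  }, double(1))
  data.frame(degree = degrees, worst_error = worst)
}
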