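# Two-compartment forward model of the diffusion-weighted signal.
#
# One voxel's signal is modelled as two non-exchanging pools:
#
#   S(b, g) = S0 * [ (1 - nu) * exp(-b * D_eff)
#                    + nu * exp(-b * D_T) *
#                      sum_lm f_lm * k_l(b * (D_L - D_T)) * Y_lm(g) ]
#
# The first term is hindered, Gaussian and isotropic (cell bodies, glia,
# extracellular space) with effective diffusivity D_eff. The second is the
# neurite pool: impermeable cylindrically symmetric segments with axial
# diffusivity D_L and transverse D_T, whose axis orientations follow an ODF
# expanded in even-order real spherical harmonics f_lm; the sum over
# orientations collapses to the per-order kernel k_l (Funk-Hecke). With
# f_00 = 1/sqrt(4 pi) the ODF integrates to one and S(0) = S0 exactly.

.F00 <- 1 / sqrt(4 * pi)

#' Construct one voxel's tissue parameters
#'
#' @param s0 unweighted signal amplitude (arbitrary units)
#' @param nu neurite signal fraction in `[0, 1]`
#' @param d_eff effective isotropic diffusivity of the non-neurite pool,
#'   mm^2/s
#' @param d_long,d_trans diffusivity along / transverse to the neurite
#'   axis, mm^2/s, with `0 <= d_trans <= d_long`
#' @param odf_coeffs even-order real SH coefficients of the orientation
#'   distribution ((l,m)-lexicographic; length 1, 6 or 15 for orders 0, 2,
#'   4). Default is the isotropic ODF at order 4. `f_00` must equal
#'   `1/sqrt(4 pi)`.
#' @return an object of class `tissue_params`
#' @export
tissue_params <- function(s0 = 1, nu = 0.3, d_eff = 0.7e-3,
                          d_long = 1.2e-3, d_trans = 0.1e-3,
                          odf_coeffs = NULL) {
  if (is.null(odf_coeffs)) odf_coeffs <- c(.F00, rep(0, 14))
  n_c <- length(odf_coeffs)
  l_max <- switch(as.character(n_c), `1` = 0L, `6` = 2L, `15` = 4L,
                  `28` = 6L, `45` = 8L,
                  stop("odf_coeffs length ", n_c,
                       " is not a complete even-order basis"))
  if (!is.finite(s0) || s0 < 0) stop("s0 must be non-negative")
  if (!is.finite(nu) || nu < 0 || nu > 1) stop("nu must lie in [0, 1]")
  if (d_eff < 0) stop("d_eff must be non-negative")
  if (d_trans < 0 || d_trans > d_long)
    stop("need 0 <= d_trans <= d_long")
  if (abs(odf_coeffs[1L] - .F00) > 1e-6)
    stop("f_00 must equal 1/sqrt(4 pi) so the ODF integrates to 1")
  structure(list(s0 = s0, nu = nu, d_eff = d_eff, d_long = d_long,
                 d_trans = d_trans, odf_coeffs = as.double(odf_coeffs),
                 l_max = l_max),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "Tissue params: nu=%.3f  D_eff=%.3g  D_L=%.3g  D_T=%.3g mm^2/s  (l_max=%d)\n",
    x$nu, x$d_eff, x$d_long, x$d_trans, x$l_max))
  invisible(x)
}

#' Truncated-delta ODF coefficients for a coherent fiber population
#'
#' Projection of a (antipodally symmetrized) delta function at `axis` onto
#' the even-order basis: `f_lm = Y_lm(axis)`. This is the band-limited
#' representation of a perfectly coherent orientation distribution.
#'
#' An optional spherical heat-kernel smoothing damps order `l` by
#' `exp(-smoothing * l * (l + 1))`. The raw truncation rings (negative
#' lobes of ~11% of the peak at order 4, and slightly negative predicted
#' signals at high b perpendicular to the axis); `smoothing = 0.06` is the
#' smallest round level at which predicted magnitudes stay positive for
#' fixed-tissue diffusivities, and is what the phantom's coherent layers
#' use.
#'
#' @param axis unit 3-vector
#' @param l_max even order of the expansion
#' @param smoothing heat-kernel time; 0 gives the pure truncated delta
#' @return coefficient vector usable as `odf_coeffs` in [tissue_params()]
#' @export
odf_delta_coeffs <- function(axis, l_max = 4L, smoothing = 0) {
  axis <- axis / sqrt(sum(axis^2))
  f <- as.vector(sh_basis(matrix(axis, 1L), l_max))
  if (smoothing > 0) {
    idx <- sh_index_table(l_max)
    f <- f * exp(-smoothing * idx$l * (idx$l + 1))
  }
  f
}

#' Predict the diffusion-weighted signal of one voxel
#'
#' @param params a [tissue_params()]
#' @param scheme an [acquisition_scheme()]
#' @return numeric vector of predicted signals, one per measurement
#' @export
predict_signal <- function(params, scheme) {
  if (!inherits(params, "tissue_params")) stop("params must be tissue_params")
  if (!inherits(scheme, "acquisition_scheme"))
    stop("scheme must be an acquisition_scheme")
  b <- scheme$bvals
  iso <- exp(-b * params$d_eff)
  if (params$nu == 0)
    return(params$s0 * iso)
  Y <- sh_basis(scheme$bvecs, params$l_max)
  neur <- .neurite_signal(params, b, Y)
  params$s0 * ((1 - params$nu) * iso + params$nu * neur)
}

# Neurite-pool signal (unit amplitude) given precomputed basis values.
.neurite_signal <- function(params, b, Y) {
  idx <- sh_index_table(params$l_max)
  alpha <- b * (params$d_long - params$d_trans)
  ub <- unique(b)
  K <- kernel_coeffs(unique(alpha), params$l_max)
  K <- K[match(alpha, unique(alpha)), , drop = FALSE]
  lpos <- match(idx$l, seq(0L, params$l_max, by = 2L))
  w <- K[, lpos, drop = FALSE] *
    matrix(params$odf_coeffs, nrow(K), nrow(idx), byrow = TRUE)
  exp(-b * params$d_trans) * rowSums(w * Y)
}

#' Near-uniform sphere grid (Fibonacci spiral)
#'
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Brute-force signal by direct sphere quadrature
#'
#' Testing oracle for [predict_signal()]: reconstructs the ODF from its
#' coefficients on a dense near-uniform grid and integrates the
#' single-cylinder response numerically instead of using the Funk-Hecke
#' reduction. Agreement within 1e-4 relative is expected for
#' `n_sphere_points >= 1e4`.
#'
#' Band-limited representations of sharp distributions necessarily ring:
#' a truncated delta at order 4 dips to about -11% of its peak. The
#' negativity guard therefore rejects only *strongly* negative
#' reconstructions (beyond `max_negative` times the peak), which catches
#' invalid coefficient sets without refusing legitimate coherent ODFs.
#'
#' @param params a [tissue_params()]
#' @param scheme an [acquisition_scheme()]
#' @param n_sphere_points number of quadrature nodes
#' @param max_negative reject when `min(ODF) < -max_negative * max(ODF)`
#' @return numeric vector of signals, one per measurement
#' @export
brute_force_signal <- function(params, scheme, n_sphere_points = 10000L,
                               max_negative = 0.25) {
  if (params$nu == 0) return(predict_signal(params, scheme))
  grid <- fibonacci_sphere(n_sphere_points)
  odf <- as.vector(sh_basis(grid, params$l_max) %*% params$odf_coeffs)
  if (min(odf) < -max_negative * max(abs(odf)))
    stop("reconstructed ODF is strongly negative (min = ",
         signif(min(odf), 3), "); invalid coefficient set")
  w <- 4 * pi / n_sphere_points
  b <- scheme$bvals
  alpha <- b * (params$d_long - params$d_trans)
  ct2 <- (scheme$bvecs %*% t(grid))^2          # n_meas x n_grid
  neur <- exp(-b * params$d_trans) *
    as.vector(exp(-alpha * ct2) %*% odf) * w
  iso <- exp(-b * params$d_eff)
  params$s0 * ((1 - params$nu) * iso + params$nu * neur)
}
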