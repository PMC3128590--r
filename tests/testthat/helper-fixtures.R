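# Shared fixtures: everything is generated in code, nothing read from disk
# except the two packaged text tables.

coherent_odf <- function(axis = c(0, 0, 1))
  odf_delta_coeffs(axis, 4L, smoothing = 0.06)

# Random tissue parameters in a physiologically identifiable regime
# (fixed-tissue diffusivities, clear contrast between the neurite and
# isotropic pools so that nu is well determined by noise-free data).
random_valid_params <- function(seed) {
  set.seed(seed)
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  odf <- if (stats::runif(1) < 0.3) NULL else
    odf_delta_coeffs(axis, 4L, smoothing = stats::runif(1, 0.06, 0.2))
  tissue_params(s0 = stats::runif(1, 0.5, 2),
                nu = stats::runif(1, 0.05, 0.7),
                d_eff = stats::runif(1, 0.5e-3, 1.2e-3),
                d_long = stats::runif(1, 0.9e-3, 1.6e-3),
                d_trans = stats::runif(1, 0.05e-3, 0.3e-3),
                odf_coeffs = odf)
}

# A rotation matrix with determinant +1, seeded.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R * sign(det(R))
}

# Ground-truth draw from the phantom's stated world: fixed-tissue
# diffusivities, neurite density spanning the reference table's range
# (0.23-0.43 across layers and groups), 3 of 10 layers isotropic (the
# cell-body layers), coherent layers minimally smoothed.
random_phantom_truth <- function(seed) {
  set.seed(seed)
  nu <- stats::runif(1, 0.2, 0.5)
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  odf <- if (stats::runif(1) < 0.3) NULL else
    odf_delta_coeffs(axis, 4L, smoothing = 0.06)
  tissue_params(s0 = 1, nu = nu, d_eff = 0.7e-3, d_long = 1.2e-3,
                d_trans = 0.1e-3, odf_coeffs = odf)
}

tiny_design <- function(..., snr_b0 = Inf, seed = 1L)
  study_design(n_per_group = 2L, snr_b0 = snr_b0, seed = seed,
               band_width = 1L, n_cols = 2L, ...)

add_rician <- function(signal, sigma, seed) {
  set.seed(seed)
  sqrt((signal + stats::rnorm(length(signal), 0, sigma))^2 +
         stats::rnorm(length(signal), 0, sigma)^2)
}
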