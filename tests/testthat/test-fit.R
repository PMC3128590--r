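sch <- default_scheme()

test_that("dti_init recovers tensors exactly from noise-free signal", {
  # isotropic Gaussian decay
  s_iso <- exp(-sch$bvals * 1.0e-3)
  di <- dti_init(s_iso, sch)
  expect_equal(di$md, 1.0e-3, tolerance = 1e-9)
  expect_equal(di$fa, 0, tolerance = 1e-6)
  expect_equal(di$params$nu, 0, tolerance = 1e-6)
  # prolate tensor
  D <- diag(c(1.5e-3, 0.2e-3, 0.2e-3))
  s_pro <- exp(-sch$bvals * rowSums((sch$bvecs %*% D) * sch$bvecs))
  dp <- dti_init(s_pro, sch)
  expect_equal(dp$eigenvalues, c(1.5e-3, 0.2e-3, 0.2e-3), tolerance = 1e-9)
  expect_equal(dp$params$d_long, 1.5e-3, tolerance = 1e-9)
  expect_equal(dp$params$d_trans, 0.2e-3, tolerance = 1e-9)
})

test_that("dti_init rejects degenerate input", {
  expect_error(dti_init(rep(0, 54), sch), "not all zero")
  few <- acquisition_scheme(c(0, rep(5000, 53)),
                            default_directions())
  expect_error(dti_init(rep(1, 54), few), "at least 7")
})

test_that("fit_voxel recovers known parameters from noise-free signal", {
  truth <- tissue_params(s0 = 1, nu = 0.4, d_eff = 0.7e-3, d_long = 1.2e-3,
                         d_trans = 0.1e-3, odf_coeffs = coherent_odf())
  fr <- fit_voxel(predict_signal(truth, sch), sch)
  expect_true(fr$converged)
  expect_lt(abs(fr$params$nu - 0.4), 1e-3)
  expect_lt(abs(fr$params$d_eff - 0.7e-3), 2e-5)
  # isotropic-ODF voxel (cell layer regime)
  iso <- tissue_params(s0 = 1, nu = 0.25, d_eff = 0.7e-3, d_long = 1.2e-3,
                       d_trans = 0.1e-3)
  fi <- fit_voxel(predict_signal(iso, sch), sch)
  expect_lt(abs(fi$params$nu - 0.25), 1e-3)
  # identifiable null case
  null <- tissue_params(s0 = 1, nu = 0, d_eff = 1e-3)
  fn <- fit_voxel(predict_signal(null, sch), sch)
  expect_lte(fn$params$nu, 0.02)
})

test_that("fit_voxel is deterministic and order-invariant", {
  truth <- tissue_params(nu = 0.4, odf_coeffs = coherent_odf())
  sig <- add_rician(predict_signal(truth, sch), 0.01, seed = 11)
  f1 <- fit_voxel(sig, sch, seed = 7L)
  f2 <- fit_voxel(sig, sch, seed = 7L)
  expect_identical(f1, f2)
  # permuting the measurements does not change the result
  set.seed(3)
  perm <- sample(54L)
  sch_p <- acquisition_scheme(sch$bvals[perm], sch$bvecs[perm, ],
                              sch$big_delta, sch$small_delta, sch$n_averages)
  f3 <- fit_voxel(sig[perm], sch_p, seed = 7L)
  expect_equal(f3$params$nu, f1$params$nu, tolerance = 1e-10)
  expect_equal(f3$params$d_eff, f1$params$d_eff, tolerance = 1e-10)
})

test_that("multi-start never does worse than the single tensor start", {
  truth <- tissue_params(nu = 0.3, odf_coeffs = coherent_odf())
  sig <- add_rician(predict_signal(truth, sch), 0.02, seed = 5)
  multi <- fit_voxel(sig, sch, fit_config(n_starts = 5L))
  single <- fit_voxel(sig, sch, fit_config(n_starts = 1L))
  expect_lte(multi$objective, single$objective + 1e-12)
})

test_that("noisy fits stay accurate at SNR 50", {
  truth <- tissue_params(nu = 0.4, odf_coeffs = coherent_odf())
  clean <- predict_signal(truth, sch)
  sigma <- 1 / 50 / sqrt(4)   # b0 SNR 50, four averages
  errs <- vapply(1:40, function(i) {
    fit_voxel(add_rician(clean, sigma, seed = i), sch)$params$nu - 0.4
  }, double(1))
  expect_lt(median(abs(errs)), 0.05)
})

test_that("fit_volume fits within the mask and isolates bad voxels", {
  dims <- c(3, 2, 1)
  nus <- array(seq(0.1, 0.45, length.out = 6L), dims)
  sig <- array(0, c(dims, 54L))
  for (i in 1:prod(dims)) {
    p <- tissue_params(nu = as.vector(nus)[i], odf_coeffs = coherent_odf())
    sig[(i - 1) %% 3 + 1, (i - 1) %/% 3 + 1, 1, ] <- predict_signal(p, sch)
  }
  vol <- dwi_volume(sig, sch)
  maps <- fit_volume(vol, config = fit_config(), quiet = TRUE)
  expect_true(all(maps$converged == 1))
  expect_lt(max(abs(maps$neurite_density - nus)), 1e-3)

  # empty mask: no fits, no error
  empty <- fit_volume(vol, mask = array(FALSE, dims), quiet = TRUE)
  expect_true(all(is.na(empty$neurite_density)))

  # a NaN voxel is flagged unconverged, neighbours unaffected
  sig_bad <- sig
  sig_bad[1, 1, 1, 3] <- NaN
  vol_bad <- dwi_volume(sig_bad, sch)
  maps_bad <- fit_volume(vol_bad, quiet = TRUE)
  expect_identical(maps_bad$converged[1, 1, 1], 0)
  expect_true(is.na(maps_bad$neurite_density[1, 1, 1]))
  expect_equal(maps_bad$neurite_density[2:3, , 1], maps$neurite_density[2:3, , 1],
               tolerance = 1e-12)

  expect_error(fit_volume(vol, mask = array(TRUE, c(2, 2, 1))), "mask")
})

test_that("parameter maps survive a NIfTI round trip", {
  dims <- c(2, 2, 1)
  sig <- array(0, c(dims, 54L))
  for (i in 1:4) {
    p <- tissue_params(nu = 0.1 * i, odf_coeffs = coherent_odf())
    sig[(i - 1) %% 2 + 1, (i - 1) %/% 2 + 1, 1, ] <- predict_signal(p, sch)
  }
  mask <- array(c(TRUE, TRUE, TRUE, FALSE), dims)
  maps <- fit_volume(dwi_volume(sig, sch), mask, quiet = TRUE)
  dir <- tempfile()
  write_parameter_maps(maps, dir)
  back <- read_parameter_maps(dir)
  expect_equal(back$neurite_density, maps$neurite_density, tolerance = 1e-12)
  expect_true(is.na(back$neurite_density[2, 2, 1]))
  unlink(dir, recursive = TRUE)
})
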