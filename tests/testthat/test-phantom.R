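test_that("default layer table mirrors the packaged reference levels", {
  lay <- default_layers()
  expect_equal(nrow(lay), 10L)
  expect_identical(lay$region, rep(c("CA1", "CA3", "DG"), c(4, 4, 2)))
  expect_identical(lay$subregion[lay$region == "DG"], c("GL", "ML"))
  expect_identical(lay$odf_mode[lay$subregion %in% c("CL", "GL")],
                   rep("isotropic", 3L))
  # mean +- 3 SD inside [0, 1] for every cell
  expect_true(all(lay$stressed_mean + 3 * lay$stressed_sd <= 1))
  expect_true(all(lay$control_mean - 3 * lay$control_sd >= 0))
})

test_that("label map construction is deterministic and scales", {
  lay <- default_layers()
  lm1 <- make_labelmap(lay, band_width = 2L, n_cols = 6L)
  expect_identical(sort(unique(as.vector(lm1$labels))), 1:10)
  counts1 <- table(lm1$labels)
  lm2 <- make_labelmap(lay, band_width = 4L, n_cols = 6L)
  expect_identical(as.vector(table(lm2$labels)), 2L * as.vector(counts1))
  only_sr <- make_labelmap(lay[lay$subregion == "SR", ], band_width = 2L)
  expect_identical(unique(as.vector(only_sr$labels)),
                   lay$label[lay$subregion == "SR"])
  expect_error(make_labelmap(lay[0, ]), "no layers")
  expect_error(make_labelmap(lay, band_width = 0L), "at least one voxel")
})

test_that("noise-free zero-spread subjects reproduce the forward model exactly", {
  lay <- default_layers()
  lay$control_sd <- 0
  des <- tiny_design(seed = 9L)
  sub <- simulate_subject(lay, "control", des)
  lm <- sub$labelmap
  for (i in c(1L, 7L)) {   # a coherent and another coherent/iso layer
    odf <- if (lay$odf_mode[i] == "coherent") coherent_odf() else NULL
    p <- tissue_params(s0 = 1, nu = lay$control_mean[i],
                       d_eff = lay$d_eff[i], d_long = lay$d_long[i],
                       d_trans = lay$d_trans[i], odf_coeffs = odf)
    want <- predict_signal(p, des$scheme)
    vox <- which(lm$labels == lay$label[i], arr.ind = TRUE)[1, ]
    expect_equal(sub$volume$signal[vox[1], vox[2], vox[3], ], want,
                 tolerance = 1e-12)
  }
  expect_identical(sub$truth$nu_true, lay$control_mean)
})

test_that("subject simulation is seed-deterministic", {
  lay <- default_layers()
  des <- tiny_design(snr_b0 = 50, seed = 4L)
  a <- simulate_subject(lay, "stressed", des, seed = 123L)
  b <- simulate_subject(lay, "stressed", des, seed = 123L)
  expect_identical(a$volume$signal, b$volume$signal)
  c <- simulate_subject(lay, "stressed", des, seed = 124L)
  expect_false(identical(a$volume$signal, c$volume$signal))
})

test_that("background voxels follow the Rayleigh law and the noise floor holds", {
  lay <- default_layers()[1:2, ]
  des <- study_design(n_per_group = 2L, snr_b0 = 50, seed = 2L,
                      band_width = 1L, n_cols = 2L)
  # custom label map with a large zero-signal background region
  lm <- make_labelmap(lay, band_width = 1L, n_cols = 2L)
  lab <- array(0L, c(2, 1000, 1))
  lab[1:2, 1:2, 1] <- lm$labels[, , 1]
  lm$labels <- lab
  sub <- simulate_subject(lay, "control", des, labelmap = lm, seed = 31L)
  sigma <- 1 / 50 / sqrt(4)
  bg <- sub$volume$signal[, 3:1000, , ]   # >= 1e5 pure-noise draws
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.01)
  # b = 15000 mean never sinks below the Rician floor
  des2 <- study_design(n_per_group = 2L, snr_b0 = 50, seed = 2L,
                       band_width = 8L, n_cols = 8L)
  sub2 <- simulate_subject(default_layers(), "stressed", des2, seed = 8L)
  hi <- sub2$volume$signal[, , , des2$scheme$bvals == 15000]
  expect_gte(mean(hi), sigma * sqrt(pi / 2) * 0.95)
})

test_that("study simulation has the right structure and determinism", {
  lay <- default_layers()
  des <- tiny_design(seed = 21L)
  st <- simulate_study(lay, des)
  expect_length(st$subjects, 4L)
  expect_identical(vapply(st$subjects, `[[`, character(1), "group"),
                   rep(c("control", "stressed"), each = 2L))
  expect_equal(nrow(st$truth), 4L * 10L)
  # zero spread + no noise: subjects within a group are identical
  lay0 <- lay
  lay0$control_sd <- lay0$stressed_sd <- 0
  st0 <- simulate_study(lay0, des)
  expect_identical(st0$subjects[[1]]$volume$signal,
                   st0$subjects[[2]]$volume$signal)
  # different master seeds give different draws
  st2 <- simulate_study(lay, tiny_design(seed = 22L))
  expect_false(identical(st$subjects[[1]]$volume$signal,
                         st2$subjects[[1]]$volume$signal))
})

test_that("study directories round-trip through write_study/read_study", {
  dir <- tempfile()
  st <- simulate_study(default_layers(), tiny_design(seed = 13L))
  write_study(st, dir)
  back <- read_study(dir)
  expect_length(back$subjects, 4L)
  expect_identical(back$subjects[[1]]$volume$signal,
                   st$subjects[[1]]$volume$signal)
  expect_identical(back$labelmap$labels, st$labelmap$labels)
  expect_equal(back$truth$nu_true, st$truth$nu_true, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
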