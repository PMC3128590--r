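# Layered hippocampal phantom: a schematic two-group study generator.
#
# The phantom replaces ex-vivo data for testing. Geometry is a slab of
# parallel laminar bands — one band per hippocampal subregion (CA1 and CA3
# stratum oriens / pyramidal cell layer / stratum radiatum / stratum
# lacunosum-moleculare, dentate gyrus granule cell and molecular layers) —
# since the downstream analysis only consumes ROI labels, not anatomy.
# Per-layer neurite densities and their between-subject spread default to
# the mean +- SD levels of the study this pipeline emulates; diffusivities
# default to typical fixed-tissue values and are held constant across
# subjects (only nu carries between-subject variability). Cell layers (CL,
# GL) use an isotropic ODF: there the non-neurite pool dominates and no
# coherent axis exists.

#' Default layer specification table
#'
#' One row per subregion with group-wise neurite-density means/SDs (loaded
#' from the packaged reference table), shared ground-truth diffusivities
#' (mm^2/s) and the ODF mode ("coherent" for dendritic strata, "isotropic"
#' for cell-body layers).
#'
#' @param d_eff,d_long,d_trans ground-truth diffusivities applied to every
#'   layer, mm^2/s
#' @return data.frame of class `layer_spec`
#' @export
default_layers <- function(d_eff = 0.7e-3, d_long = 1.2e-3,
                           d_trans = 0.1e-3) {
  path <- system.file("extdata", "table1_neurite_density.csv",
                      package = "neuritemap", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$label <- seq_len(nrow(tab))
  tab$d_eff <- d_eff
  tab$d_long <- d_long
  tab$d_trans <- d_trans
  tab$odf_mode <- ifelse(tab$subregion %in% c("CL", "GL"),
                         "isotropic", "coherent")
  ok <- tab$stressed_mean - 3 * tab$stressed_sd >= 0 &
    tab$stressed_mean + 3 * tab$stressed_sd <= 1 &
    tab$control_mean - 3 * tab$control_sd >= 0 &
    tab$control_mean + 3 * tab$control_sd <= 1
  stopifnot(all(ok))
  class(tab) <- c("layer_spec", "data.frame")
  tab
}

#' Study design for the phantom
#'
#' @param n_per_group subjects per group (>= 2)
#' @param snr_b0 Rician signal-to-noise ratio at b = 0 (`Inf` = noise-free)
#' @param seed master seed; all subject draws derive from it
#' @param scheme acquisition to simulate
#' @param band_width voxels per layer band (rows)
#' @param n_cols slab width in voxels
#' @param n_slices slab thickness in voxels
#' @param s0 unweighted signal amplitude
#' @return object of class `study_design`
#' @export
study_design <- function(n_per_group = 4L, snr_b0 = 50, seed = 1L,
                         scheme = default_scheme(), band_width = 2L,
                         n_cols = 6L, n_slices = 1L, s0 = 1) {
  if (n_per_group < 2L) stop("n_per_group must be at least 2")
  if (!(snr_b0 > 0)) stop("snr_b0 must be positive (or Inf for noise-free)")
  if (band_width < 1L || n_cols < 1L || n_slices < 1L)
    stop("geometry must give every layer at least one voxel")
  structure(list(n_per_group = as.integer(n_per_group), snr_b0 = snr_b0,
                 seed = as.integer(seed), scheme = scheme,
                 band_width = as.integer(band_width),
                 n_cols = as.integer(n_cols),
                 n_slices = as.integer(n_slices), s0 = s0),
            class = "study_design")
}

#' Build the laminar label map
#'
#' Layer `i` of `layers` occupies a band of `band_width` rows spanning the
#' full slab width; labels are the `label` column. Deterministic. Doubling
#' `band_width` exactly doubles every per-layer voxel count.
#'
#' @param layers a [default_layers()]-style table (possibly subset)
#' @param band_width,n_cols,n_slices slab geometry, voxels
#' @return object of class `label_map`: integer 3-D `labels` array plus
#'   `names` and `regions` (label-indexed character vectors)
#' @export
make_labelmap <- function(layers = default_layers(), band_width = 2L,
                          n_cols = 6L, n_slices = 1L) {
  if (nrow(layers) < 1L) stop("no layers requested")
  if (band_width < 1L || n_cols < 1L || n_slices < 1L)
    stop("every layer needs at least one voxel")
  n_rows <- nrow(layers) * band_width
  lab <- array(0L, c(n_rows, n_cols, n_slices))
  for (i in seq_len(nrow(layers))) {
    rows <- ((i - 1L) * band_width + 1L):(i * band_width)
    lab[rows, , ] <- layers$label[i]
  }
  nm <- stats::setNames(layers$subregion, layers$label)
  rg <- stats::setNames(layers$region, layers$label)
  structure(list(labels = lab, names = nm, regions = rg),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("Label map:", paste(dim(x$labels), collapse = " x "), "voxels,",
      length(x$names), "labelled layers\n")
  invisible(x)
}

# Truncated-normal draw on [0, 1] by rejection (the defaults keep
# mean +- 3 SD inside the interval, so rejection is rare).
.rtruncnorm01 <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

#' Simulate one subject's diffusion-weighted volume
#'
#' Draws the subject's per-layer neurite density from the group's
#' (mean, SD) truncated to `[0, 1]`, fills each layer's voxels with the
#' forward-model signal, and applies Rician noise:
#' `observed = sqrt((S + e1)^2 + e2^2)` with
#' `e ~ N(0, s0 / snr_b0 / sqrt(n_averages))` — the 1/sqrt(n) factor
#' emulating per-direction signal averaging. Background (label 0) voxels
#' contain pure noise. Deterministic given `seed`.
#'
#' @param layers layer table
#' @param group `"control"` or `"stressed"`
#' @param design a [study_design()]
#' @param labelmap a [make_labelmap()] result (built from `design` when
#'   `NULL`)
#' @param seed subject seed (defaults to the design's master seed)
#' @return list with `volume` ([dwi_volume()]), `truth` (per-layer drawn
#'   nu), and `labelmap`
#' @export
simulate_subject <- function(layers, group = c("control", "stressed"),
                             design = study_design(), labelmap = NULL,
                             seed = design$seed) {
  group <- match.arg(group)
  if (is.null(labelmap))
    labelmap <- make_labelmap(layers, design$band_width, design$n_cols,
                              design$n_slices)
  scheme <- design$scheme
  n_meas <- length(scheme)
  d <- dim(labelmap$labels)
  mcol <- if (group == "stressed") "stressed_mean" else "control_mean"
  scol <- if (group == "stressed") "stressed_sd" else "control_sd"

  .with_seed(seed, {
    nu_draw <- vapply(seq_len(nrow(layers)), function(i)
      .rtruncnorm01(layers[[mcol]][i], layers[[scol]][i]), double(1))
    sig <- array(0, c(d, n_meas))
    flat <- matrix(sig, prod(d), n_meas)
    for (i in seq_len(nrow(layers))) {
      odf <- if (layers$odf_mode[i] == "coherent")
        odf_delta_coeffs(c(0, 0, 1), 4L, smoothing = 0.06) else NULL
      p <- tissue_params(s0 = design$s0, nu = nu_draw[i],
                         d_eff = layers$d_eff[i],
                         d_long = layers$d_long[i],
                         d_trans = layers$d_trans[i],
                         odf_coeffs = odf)
      s <- predict_signal(p, scheme)
      vox <- which(labelmap$labels == layers$label[i])
      flat[vox, ] <- matrix(s, length(vox), n_meas, byrow = TRUE)
    }
    if (is.finite(design$snr_b0)) {
      sigma <- design$s0 / design$snr_b0 / sqrt(scheme$n_averages)
      e1 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat))
      e2 <- matrix(stats::rnorm(length(flat), 0, sigma), nrow(flat))
      flat <- sqrt((flat + e1)^2 + e2^2)
    }
    truth <- data.frame(label = layers$label, region = layers$region,
                        subregion = layers$subregion, group = group,
                        nu_true = nu_draw)
    list(volume = dwi_volume(array(flat, c(d, n_meas)), scheme,
                             voxel_size = c(0.07, 0.07, 0.32)),
         truth = truth, labelmap = labelmap)
  })
}

#' Simulate a full two-group study
#'
#' `n_per_group` subjects per group, each with an independent seed derived
#' deterministically from the design's master seed, sharing one label map.
#'
#' @param layers layer table (defaults to the packaged reference levels)
#' @param design a [study_design()]
#' @return object of class `phantom_study`: `subjects` (list with `id`,
#'   `group`, `volume`, `truth`), `labelmap`, `design`, `layers`, and
#'   `truth` (all subjects' per-layer ground truth, row-bound)
#' @export
simulate_study <- function(layers = default_layers(),
                           design = study_design()) {
  labelmap <- make_labelmap(layers, design$band_width, design$n_cols,
                            design$n_slices)
  n <- design$n_per_group
  seeds <- .with_seed(design$seed,
                      sample.int(.Machine$integer.max - 1L, 2L * n))
  groups <- rep(c("control", "stressed"), each = n)
  ids <- sprintf("sub-%s%02d", ifelse(groups == "control", "c", "s"),
                 rep(seq_len(n), 2L))
  subjects <- lapply(seq_len(2L * n), function(i) {
    s <- simulate_subject(layers, groups[i], design, labelmap,
                          seed = seeds[i])
    list(id = ids[i], group = groups[i], volume = s$volume,
         truth = transform(s$truth, subject = ids[i]))
  })
  truth <- do.call(rbind, lapply(subjects, `[[`, "truth"))
  structure(list(subjects = subjects, labelmap = labelmap,
                 design = design, layers = layers, truth = truth),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("Phantom study:", length(x$subjects), "subjects (",
      x$design$n_per_group, "per group ),", nrow(x$layers), "layers\n")
  invisible(x)
}

#' Write a phantom study to a directory
#'
#' Per-subject NIfTI + bval/bvec, the shared label map, ground-truth CSV
#' and the design as YAML.
#'
#' @param study a [simulate_study()] result
#' @param dir output directory
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in study$subjects) {
    base <- file.path(dir, s$id)
    write_dwi(s$volume, paste0(base, "_dwi.nii.gz"),
              paste0(base, ".bval"), paste0(base, ".bvec"))
  }
  write_nifti(study$labelmap$labels, file.path(dir, "labelmap.nii.gz"),
              pixdim = study$subjects[[1L]]$volume$voxel_size,
              datatype = "int32")
  utils::write.csv(study$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(study$layers, file.path(dir, "layers.csv"),
                   row.names = FALSE)
  des <- study$design
  yaml::write_yaml(list(
    n_per_group = des$n_per_group, snr_b0 = des$snr_b0, seed = des$seed,
    band_width = des$band_width, n_cols = des$n_cols,
    n_slices = des$n_slices, s0 = des$s0,
    subjects = lapply(study$subjects, function(s)
      list(id = s$id, group = s$group))),
    file.path(dir, "design.yaml"))
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory
#' @return list with `subjects` (id, group, volume), `labelmap`, `layers`,
#'   `truth`, `design` (raw YAML list)
#' @export
read_study <- function(dir) {
  des <- yaml::read_yaml(file.path(dir, "design.yaml"))
  layers <- utils::read.csv(file.path(dir, "layers.csv"),
                            stringsAsFactors = FALSE)
  lab_img <- read_nifti(file.path(dir, "labelmap.nii.gz"))
  labelmap <- structure(list(
    labels = array(as.integer(lab_img$data), dim(lab_img$data)),
    names = stats::setNames(layers$subregion, layers$label),
    regions = stats::setNames(layers$region, layers$label)),
    class = "label_map")
  subjects <- lapply(des$subjects, function(s) {
    base <- file.path(dir, s$id)
    bvec <- paste0(base, ".bvec")
    vol <- read_dwi(paste0(base, "_dwi.nii.gz"), paste0(base, ".bval"),
                    bvec, n_averages = 4L)
    list(id = s$id, group = s$group, volume = vol)
  })
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  list(subjects = subjects, labelmap = labelmap, layers = layers,
       truth = truth, design = des)
}
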