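# Voxel-wise estimation of the two-compartment model.
#
# The fit is a bound-constrained nonlinear least-squares problem solved by
# variable projection: the optimizer searches only the three diffusivities
# (d_eff, d_long and the ratio d_trans/d_long, each box-bounded), and for
# every candidate the amplitudes — the isotropic weight S0*(1-nu) and the
# neurite coefficients S0*nu*f_lm — are the exact solution of a linear
# least-squares subproblem. This keeps the nonlinear search 3-dimensional
# (fast, and far less multi-modal than the 19-parameter joint problem)
# while remaining a Gaussian-noise least-squares estimator of the same
# model. Non-negativity of the two compartment amplitudes is enforced by
# refitting with the offending compartment removed.

#' Fitting configuration
#'
#' @param l_max even spherical-harmonic order of the ODF expansion. The
#'   default 4 (15 coefficients) keeps the voxel problem overdetermined
#'   with 54 measurements.
#' @param n_starts number of optimizer starts: the tensor-based start plus
#'   `n_starts - 1` seeded multiplicative perturbations (+-20%) of its
#'   diffusivities
#' @param seed integer seed making the perturbations reproducible
#' @param d_max upper bound on all diffusivities, mm^2/s
#' @param max_iterations L-BFGS-B iteration cap per start
#' @param convergence_tol relative objective-improvement tolerance
#' @return an object of class `fit_config`
#' @export
fit_config <- function(l_max = 4L, n_starts = 5L, seed = 1L, d_max = 4e-3,
                       max_iterations = 100L, convergence_tol = 1e-12) {
  if (l_max %% 2L != 0L) stop("l_max must be even")
  if (n_starts < 1L) stop("n_starts must be positive")
  if (!(d_max > 0) || !(convergence_tol > 0) || max_iterations < 1L)
    stop("invalid fit configuration")
  structure(list(l_max = as.integer(l_max), n_starts = as.integer(n_starts),
                 seed = as.integer(seed), d_max = d_max,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "fit_config")
}

# Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Log-linear diffusion tensor fit
#'
#' Fits `log S = log S0 - b g' D g` by linear least squares on the
#' low-b rows (b <= 4000 s/mm^2, where the tensor model is adequate) and
#' derives mean diffusivity, fractional anisotropy and an initial guess
#' for the two-compartment fit: `nu0 = min(1, FA)`, `d_long0`/`d_trans0`
#' the extreme eigenvalues, `d_eff0 = MD`, isotropic initial ODF.
#'
#' @param signal non-negative signal vector, one entry per measurement
#' @param scheme an [acquisition_scheme()]
#' @return list with `params` ([tissue_params()]), `md`, `fa`,
#'   `eigenvalues`
#' @export
dti_init <- function(signal, scheme) {
  use <- scheme$bvals <= 4000
  b <- scheme$bvals[use]
  g <- scheme$bvecs[use, , drop = FALSE]
  y <- signal[use]
  if (sum(use) < 7L) stop("need at least 7 measurements with b <= 4000")
  if (all(y <= 0) || !all(is.finite(y))) stop("signal must be finite and not all zero")
  dwg <- g[b > 0, , drop = FALSE]
  if (qr(dwg)$rank < 3L || nrow(unique(round(abs(dwg), 6))) < 6L)
    stop("need >= 6 non-collinear diffusion directions at b <= 4000")
  X <- cbind(1,
             -b * g[, 1L]^2, -b * g[, 2L]^2, -b * g[, 3L]^2,
             -2 * b * g[, 1L] * g[, 2L],
             -2 * b * g[, 1L] * g[, 3L],
             -2 * b * g[, 2L] * g[, 3L])
  beta <- qr.solve(X, log(pmax(y, .Machine$double.xmin)))
  D <- matrix(c(beta[2L], beta[5L], beta[6L],
                beta[5L], beta[3L], beta[7L],
                beta[6L], beta[7L], beta[4L]), 3L, 3L)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  md <- mean(ev)
  fa <- if (sum(ev^2) > 0)
    sqrt(1.5 * sum((ev - md)^2) / sum(ev^2)) else 0
  l1 <- max(ev[1L], 0)
  l3 <- min(max(ev[3L], 0), l1)
  params <- tissue_params(s0 = exp(beta[1L]),
                          nu = min(1, max(0, fa)),
                          d_eff = max(md, 0),
                          d_long = l1, d_trans = l3,
                          odf_coeffs = c(.F00, rep(0, 14)))
  list(params = params, md = md, fa = fa, eigenvalues = ev)
}

# Kernel values and their alpha-derivatives for the hot loop: same
# quantity as kernel_coeffs() (plus dk_l/dalpha = -2 pi sum c_n I_{n+2})
# without input checking or naming; series branch below alpha = 0.5.
.kernel_fast <- function(alpha, ls) {
  K <- matrix(0, length(alpha), length(ls))
  Kp <- K
  small <- alpha < 0.5
  if (any(small)) {
    for (j in seq_along(ls)) {
      s <- .kernel_series(alpha[small], ls[j])
      K[small, j] <- 2 * pi * s$k
      Kp[small, j] <- 2 * pi * s$kp
    }
  }
  if (any(!small)) {
    I <- .gauss_even_moments(alpha[!small], max(ls) + 2L)
    for (j in seq_along(ls)) {
      co <- .legendre_even_coeffs[[as.character(ls[j])]]
      sel <- seq_along(co)
      K[!small, j] <- 2 * pi * as.vector(I[, sel, drop = FALSE] %*% co)
      Kp[!small, j] <- -2 * pi * as.vector(I[, sel + 1L, drop = FALSE] %*% co)
    }
  }
  list(K = K, Kp = Kp)
}

# Variable projection at diffusivities theta = (d_eff, d_long,
# d_trans/d_long) in natural units: solves the sign-constrained linear
# subproblem for the compartment amplitudes and returns the residual sum
# of squares plus its exact gradient (Golub-Pereyra: at the linear
# solution the residual is orthogonal to the active columns, so
# d RSS / d theta_k = -2 r' (dM/d theta_k) beta). `ub`/`bidx` index the
# unique b-values so the kernel is evaluated once per shell.
.varpro_solve <- function(theta, b, Y, y, l_max, lpos, ub, bidx, ls) {
  d_eff <- theta[1L]; d_long <- theta[2L]; frac <- theta[3L]
  d_trans <- frac * d_long
  iso <- exp(-b * d_eff)
  kk <- .kernel_fast(ub * (d_long - d_trans), ls)
  KL <- kk$K[bidx, lpos, drop = FALSE]
  KpL <- kk$Kp[bidx, lpos, drop = FALSE]
  E <- exp(-b * d_trans)
  C <- E * KL * Y
  M <- cbind(iso, C)
  fit <- .lm.fit(M, y)
  beta <- fit$coefficients
  if (beta[2L] < 0) {
    # negative neurite amplitude: drop the neurite pool entirely
    a <- max(sum(iso * y) / sum(iso * iso), 0)
    beta <- c(a, rep(0, ncol(C)))
    r <- y - a * iso
  } else if (beta[1L] < 0) {
    fit2 <- .lm.fit(C, y)
    b2 <- fit2$coefficients
    if (b2[1L] < 0) {
      beta <- rep(0, ncol(M))
      r <- y
    } else {
      beta <- c(0, b2)
      r <- fit2$residuals
    }
  } else {
    r <- fit$residuals
  }
  cvec <- beta[-1L]
  if (any(cvec != 0)) {
    Yc <- Y * rep(cvec, each = nrow(Y))
    P <- rowSums(KL * Yc)      # neurite prediction / E
    Q <- rowSums(KpL * Yc)     # its alpha-derivative / E
  } else {
    P <- Q <- rep(0, length(y))
  }
  g <- c(2 * sum(r * b * iso) * beta[1L],
         -2 * sum(r * E * b * (-frac * P + (1 - frac) * Q)),
         2 * sum(r * E * b * (P + Q)) * d_long)
  list(rss = sum(r * r), beta = beta, grad = g)
}

#' Fit the two-compartment model in one voxel
#'
#' Bound-constrained nonlinear least squares (Gaussian objective) started
#' from [dti_init()] plus seeded perturbed starts; the lowest-residual
#' solution is returned. Deterministic given `seed`. Measurements are
#' internally sorted into a canonical order so the result is invariant to
#' reordering of the scheme.
#'
#' @param signal non-negative finite signal vector
#' @param scheme an [acquisition_scheme()]
#' @param config a [fit_config()]
#' @param seed overrides `config$seed` (used by [fit_volume()] to give
#'   every voxel an independent deterministic stream)
#' @return an object of class `fit_result`: `params`, `residual_norm`,
#'   `converged`, `n_function_evals`, `odf_negative`
#' @export
fit_voxel <- function(signal, scheme, config = fit_config(),
                      seed = config$seed) {
  if (!inherits(config, "fit_config")) stop("config must be a fit_config")
  if (length(signal) != length(scheme))
    stop("signal length does not match scheme")
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and non-negative")

  ord <- order(scheme$bvals, scheme$bvecs[, 1L], scheme$bvecs[, 2L],
               scheme$bvecs[, 3L])
  b <- scheme$bvals[ord]
  g <- scheme$bvecs[ord, , drop = FALSE]
  y <- signal[ord]
  sorted_scheme <- acquisition_scheme(b, g, scheme$big_delta,
                                      scheme$small_delta, scheme$n_averages)
  Y <- sh_basis(g, config$l_max)
  idx <- sh_index_table(config$l_max)
  lpos <- match(idx$l, seq(0L, config$l_max, by = 2L))
  d_max <- config$d_max

  ub <- unique(b)
  bidx <- match(b, ub)
  ls <- seq(0L, config$l_max, by = 2L)

  init <- tryCatch(dti_init(y, sorted_scheme), error = function(e) NULL)
  if (is.null(init)) {
    start0 <- c(1e-3, 1.2e-3, 0.1)
  } else {
    p <- init$params
    start0 <- c(min(p$d_eff, d_max),
                min(max(p$d_long, 1e-5), d_max),
                if (p$d_long > 0) min(p$d_trans / p$d_long, 1) else 0.1)
  }
  # Start set: the tensor start, then a fixed grid of well-separated
  # neurite diffusivity starts (the tensor start is degenerate for
  # isotropic-ODF voxels: d_long ~ d_trans makes the two compartments
  # collinear, and small perturbations cannot escape that valley), then
  # seeded +-20% perturbations when more starts are requested.
  grid <- list(c(start0[1L], 0.8e-3, 0.05), c(start0[1L], 1.6e-3, 0.05),
               c(start0[1L], 0.8e-3, 0.30), c(start0[1L], 1.6e-3, 0.30))
  starts <- c(list(start0), grid[seq_len(min(4L, config$n_starts - 1L))])
  if (config$n_starts > 5L) {
    perturb <- .with_seed(seed, {
      lapply(seq_len(config$n_starts - 5L), function(i)
        stats::runif(3, -0.2, 0.2))
    })
    for (pp in perturb) {
      s <- start0 * (1 + pp)
      starts[[length(starts) + 1L]] <-
        pmin(pmax(s, c(0, 1e-6, 0)), c(d_max, d_max, 1))
    }
  }

  # optimize in unit-scaled coordinates; fn and gr share one evaluation
  # via a single-point cache (optim calls them back to back)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  evalpt <- function(u) {
    if (!is.null(cache$u) && identical(u, cache$u)) return(cache$res)
    res <- .varpro_solve(c(u[1L] * d_max, u[2L] * d_max, u[3L]),
                         b, Y, y, config$l_max, lpos, ub, bidx, ls)
    n_evals <<- n_evals + 1L
    cache$u <- u
    cache$res <- res
    res
  }
  fn <- function(u) evalpt(u)$rss
  gr <- function(u) evalpt(u)$grad * c(d_max, d_max, 1)
  best <- NULL
  any_conv <- FALSE
  rss_floor <- 1e-10 * sum(y^2)   # numerically-exact fit: stop multistart
  for (s in starts) {
    u0 <- pmin(pmax(c(s[1L] / d_max, s[2L] / d_max, s[3L]), 1e-9), 1)
    opt <- stats::optim(u0, fn, gr, method = "L-BFGS-B",
                        lower = rep(0, 3), upper = rep(1, 3),
                        control = list(
                          maxit = config$max_iterations,
                          factr = config$convergence_tol / .Machine$double.eps))
    if (opt$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value <= rss_floor) break
  }
  # the multi-start set always contains the tensor start, so the returned
  # objective can never exceed the objective there
  # L-BFGS-B can return parameters a few ulp outside the box
  u <- pmin(pmax(best$par, 0), 1)
  theta <- c(u[1L] * d_max, u[2L] * d_max, u[3L])
  sol <- .varpro_solve(theta, b, Y, y, config$l_max, lpos, ub, bidx, ls)
  beta <- sol$beta
  s0_nu <- beta[2L] * sqrt(4 * pi)
  s0 <- beta[1L] + s0_nu
  nu <- if (s0 > 0) s0_nu / s0 else 0
  f <- if (s0_nu > 1e-12) beta[-1L] / s0_nu else rep(0, nrow(idx))
  f[1L] <- .F00
  odf_min <- min(sh_basis(fibonacci_sphere(200L), config$l_max) %*% f)
  params <- tissue_params(s0 = s0, nu = min(max(nu, 0), 1),
                          d_eff = theta[1L], d_long = theta[2L],
                          d_trans = theta[3L] * theta[2L],
                          odf_coeffs = f)
  structure(list(params = params,
                 residual_norm = sqrt(sol$rss),
                 converged = any_conv,
                 n_function_evals = n_evals,
                 odf_negative = odf_min < -1e-3,
                 objective = sol$rss),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: nu=%.3f, residual norm %.3g, %s (%d evals)\n",
              x$params$nu, x$residual_norm,
              if (x$converged) "converged" else "NOT converged",
              x$n_function_evals))
  invisible(x)
}

#' Fit the model over a masked volume
#'
#' Applies [fit_voxel()] to every in-mask voxel. Voxels outside the mask
#' are set to `NA` and excluded from the convergence mask; a voxel whose
#' signal is non-finite is flagged unconverged without affecting its
#' neighbours. Each voxel gets a deterministic seed derived from
#' `config$seed` and its linear index, so results are independent of
#' traversal order.
#'
#' @param vol a [dwi_volume()]
#' @param mask logical 3-D array aligned with the volume grid, or `NULL`
#'   for all voxels
#' @param config a [fit_config()]
#' @param quiet suppress per-slice progress messages
#' @return an object of class `parameter_maps`: 3-D arrays
#'   `neurite_density` (nu), `mean_diffusivity` (fitted d_eff, mm^2/s),
#'   `converged`, `residual_norm`, `odf_negative`
#' @export
fit_volume <- function(vol, mask = NULL, config = fit_config(),
                       quiet = FALSE) {
  if (!inherits(vol, "dwi_volume")) stop("vol must be a dwi_volume")
  d <- dim(vol$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d))
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match volume grid ", paste(d, collapse = "x"))
  nu_map <- array(NA_real_, d)
  md_map <- array(NA_real_, d)
  conv_map <- array(NA_real_, d)
  res_map <- array(NA_real_, d)
  neg_map <- array(NA_real_, d)
  sig <- matrix(vol$signal, prod(d), dim(vol$signal)[4L])
  idx_all <- which(mask)
  slice_of <- ((idx_all - 1L) %/% (d[1L] * d[2L])) + 1L
  for (z in unique(slice_of)) {
    for (i in idx_all[slice_of == z]) {
      res <- tryCatch(
        fit_voxel(sig[i, ], vol$scheme, config,
                  seed = (config$seed + i) %% .Machine$integer.max),
        error = function(e) NULL)
      if (is.null(res)) {
        conv_map[i] <- 0
      } else {
        nu_map[i] <- res$params$nu
        md_map[i] <- res$params$d_eff
        conv_map[i] <- as.numeric(res$converged)
        res_map[i] <- res$residual_norm
        neg_map[i] <- as.numeric(res$odf_negative)
      }
    }
    if (!quiet)
      message("fit_volume: slice ", z, "/", d[3L], " done (",
              sum(slice_of <= z), "/", length(idx_all), " voxels)")
  }
  structure(list(neurite_density = nu_map, mean_diffusivity = md_map,
                 converged = conv_map, residual_norm = res_map,
                 odf_negative = neg_map, voxel_size = vol$voxel_size,
                 config = config),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  n <- sum(!is.na(x$converged))
  cat("Parameter maps:", paste(dim(x$neurite_density), collapse = " x "),
      "grid;", n, "fitted voxels;",
      if (n > 0) sprintf("%.1f%% converged", 100 * mean(x$converged, na.rm = TRUE))
      else "", "\n")
  invisible(x)
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes `neurite_density.nii.gz`, `md.nii.gz`, `converged.nii.gz` and
#' `residual.nii.gz` into `dir`. `NA` sentinels (outside mask / failed
#' voxels) are stored as -1.
#'
#' @param maps a `parameter_maps` object
#' @param dir output directory (created if missing)
#' @export
write_parameter_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sub <- function(a) { a[is.na(a)] <- -1; a }
  write_nifti(sub(maps$neurite_density),
              file.path(dir, "neurite_density.nii.gz"),
              pixdim = maps$voxel_size)
  write_nifti(sub(maps$mean_diffusivity), file.path(dir, "md.nii.gz"),
              pixdim = maps$voxel_size)
  write_nifti(sub(maps$converged), file.path(dir, "converged.nii.gz"),
              pixdim = maps$voxel_size)
  write_nifti(sub(maps$residual_norm), file.path(dir, "residual.nii.gz"),
              pixdim = maps$voxel_size)
  invisible(dir)
}

#' Read parameter maps written by [write_parameter_maps()]
#'
#' @param dir directory containing the map files
#' @return a `parameter_maps` object (sentinel -1 restored to `NA`)
#' @export
read_parameter_maps <- function(dir) {
  rd <- function(f) {
    a <- read_nifti(file.path(dir, f))$data
    a[a < 0] <- NA_real_
    a
  }
  structure(list(neurite_density = rd("neurite_density.nii.gz"),
                 mean_diffusivity = rd("md.nii.gz"),
                 converged = rd("converged.nii.gz"),
                 residual_norm = rd("residual.nii.gz"),
                 odf_negative = NULL, voxel_size = NULL, config = NULL),
            class = "parameter_maps")
}
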