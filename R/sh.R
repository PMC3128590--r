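# Real even-order spherical harmonics and the Funk-Hecke kernel of the
# axially symmetric cylinder response.
#
# Basis convention (stated so coefficient files are portable): real,
# orthonormal, even orders only, columns in (l, m)-lexicographic order with
# m running -l..l; m < 0 columns carry sin(|m| phi), m > 0 carry cos(m phi),
# both with the sqrt(2) factor. Y_00 = 1/sqrt(4 pi).

#' (l, m) index table for an even-order basis
#'
#' @param l_max maximum (even) order
#' @return data.frame with one row per basis column, columns `l` and `m`
#' @export
sh_index_table <- function(l_max = 4L) {
  ls <- seq(0L, l_max, by = 2L)
  do.call(rbind, lapply(ls, function(l)
    data.frame(l = l, m = seq.int(-l, l))))
}

# Associated Legendre P_l^m(x) with the Condon-Shortley phase, m >= 0,
# vectorized over x. Standard upward recurrence in l.
.assoc_legendre <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in seq.int(m + 2L, l)) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

#' Evaluate the real even-order spherical-harmonic basis
#'
#' @param directions n x 3 matrix of unit vectors
#' @param l_max maximum order; even, at most 8
#' @return n x K matrix, K = 1, 6, 15, 28, 45 for l_max = 0, 2, 4, 6, 8;
#'   columns named `Y<l>.<m>`
#' @export
sh_basis <- function(directions, l_max = 4L) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be n x 3")
  if (l_max %% 2L != 0L || l_max < 0L || l_max > 8L)
    stop("l_max must be even and between 0 and 8")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  ct <- pmin(1, pmax(-1, directions[, 3L]))
  phi <- atan2(directions[, 2L], directions[, 1L])
  idx <- sh_index_table(l_max)
  out <- matrix(0, nrow(directions), nrow(idx))
  colnames(out) <- paste0("Y", idx$l, ".", idx$m)
  for (j in seq_len(nrow(idx))) {
    l <- idx$l[j]; m <- idx$m[j]; am <- abs(m)
    K <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    P <- .assoc_legendre(l, am, ct)
    out[, j] <- if (m == 0) K * P
                else if (m > 0) sqrt(2) * K * P * cos(m * phi)
                else sqrt(2) * K * P * sin(am * phi)
  }
  out
}

# Even monomial coefficients of the Legendre polynomials P_l(t), l even,
# as coefficients of (1, t^2, t^4, ...).
.legendre_even_coeffs <- list(
  `0` = 1,
  `2` = c(-1, 3) / 2,
  `4` = c(3, -30, 35) / 8,
  `6` = c(-5, 105, -315, 231) / 16,
  `8` = c(35, -1260, 6930, -12012, 6435) / 128
)

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Even moments I_n(a) = int_{-1}^{1} t^n exp(-a t^2) dt for n = 0,2,...,nmax,
# vectorized over a; erf closed form plus upward recurrence. Adequate for
# a >= 0.5; below that the Legendre combinations cancel catastrophically
# and the direct per-order series (.kernel_series) is used instead.
.gauss_even_moments <- function(alpha, nmax) {
  ns <- seq(0L, nmax, by = 2L)
  out <- matrix(NA_real_, length(alpha), length(ns))
  e <- exp(-alpha)
  I <- sqrt(pi / alpha) * .erf(sqrt(alpha))
  out[, 1L] <- I
  if (length(ns) > 1L) {
    for (j in 2L:length(ns)) {
      I <- ((ns[j] - 1) * I - 2 * e) / (2 * alpha)
      out[, j] <- I
    }
  }
  out
}

# int_{-1}^{1} t^(2k) P_l(t) dt for even l <= 2k (zero below the diagonal).
.legendre_moment <- function(k2, l) {
  exp((l + 1) * log(2) + lgamma(k2 + 1) + lgamma((k2 + l) / 2 + 1) -
        lgamma((k2 - l) / 2 + 1) - lgamma(k2 + l + 2))
}

# Small-alpha evaluation of k_l / (2 pi) and its alpha-derivative by the
# direct series sum_k (-alpha)^k / k! * int t^(2k) P_l dt, whose leading
# term (order alpha^(l/2)) is exact — full relative accuracy where the
# moment-combination route only achieves absolute accuracy.
.kernel_series <- function(alpha, l) {
  acc <- rep(0, length(alpha))
  accp <- acc
  for (k in (l / 2):(l / 2 + 30L)) {
    M <- .legendre_moment(2L * k, l)
    tK <- (-1)^k * alpha^k / factorial(k) * M
    acc <- acc + tK
    if (k >= 1L)
      accp <- accp + (-1)^k * alpha^(k - 1L) / factorial(k - 1L) * M
  }
  list(k = acc, kp = accp)
}

#' Funk-Hecke kernel coefficients of the cylinder response
#'
#' For an axially symmetric single-cylinder signal `exp(-alpha t^2)` (with
#' `t` the cosine between gradient and cylinder axis and
#' `alpha = b (d_long - d_trans)`), convolution with an ODF expanded in
#' spherical harmonics reduces to per-order multiplication by
#' `k_l(alpha) = 2 pi * int_{-1}^{1} exp(-alpha t^2) P_l(t) dt`.
#'
#' At `alpha = 0` this gives `k_0 = 4 pi` and `k_l = 0` for `l > 0`.
#'
#' @param alpha non-negative scalar or vector `b * (d_long - d_trans)`
#' @param l_max maximum (even) order, at most 8
#' @return matrix with one row per `alpha`, columns `k0, k2, ...`
#' @export
kernel_coeffs <- function(alpha, l_max = 4L) {
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("alpha must be finite and non-negative")
  if (l_max %% 2L != 0L || l_max > 8L)
    stop("l_max must be even and at most 8")
  ls <- seq(0L, l_max, by = 2L)
  out <- matrix(NA_real_, length(alpha), length(ls))
  colnames(out) <- paste0("k", ls)
  small <- alpha < 0.5
  if (any(small)) {
    for (j in seq_along(ls))
      out[small, j] <- 2 * pi * .kernel_series(alpha[small], ls[j])$k
  }
  if (any(!small)) {
    I <- .gauss_even_moments(alpha[!small], l_max)
    for (j in seq_along(ls)) {
      co <- .legendre_even_coeffs[[as.character(ls[j])]]
      out[!small, j] <- 2 * pi * as.vector(I[, seq_along(co), drop = FALSE] %*% co)
    }
  }
  out
}
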