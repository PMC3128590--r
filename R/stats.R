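# ROI summaries and the two-group comparison.
#
# The group test is an exact Wilcoxon rank-sum: with four subjects per
# group there are only choose(8, 4) = 70 ways to assign the mid-ranks, so
# the null distribution is enumerated in full and the two-sided p is the
# doubled smaller tail probability, capped at 1. At n = 4/4 without ties
# the achievable two-sided levels are {2/70, 4/70, 8/70, 14/70, 24/70,
# 34/70, 48/70, 62/70, 1}: the smallest, 2/70 ~= 0.029, requires complete
# separation of the two groups.

#' Per-ROI means of a parameter map
#'
#' One summary per nonzero label; non-finite (sentinel / unconverged)
#' voxels are excluded and counted.
#'
#' @param map 3-D numeric array (e.g. a neurite-density map)
#' @param labelmap a `label_map` aligned to the same grid
#' @return data.frame with columns `label`, `region`, `subregion`, `mean`,
#'   `n_voxels`, `n_excluded`
#' @export
roi_means <- function(map, labelmap) {
  if (!identical(dim(map), dim(labelmap$labels)))
    stop("map grid ", paste(dim(map), collapse = "x"),
         " does not match label map ",
         paste(dim(labelmap$labels), collapse = "x"))
  labs <- sort(unique(as.vector(labelmap$labels)))
  labs <- labs[labs != 0L]
  rows <- lapply(labs, function(l) {
    vals <- map[labelmap$labels == l]
    ok <- is.finite(vals)
    if (!any(ok))
      stop("ROI label ", l, " (", labelmap$names[as.character(l)],
           ") has no finite voxels")
    data.frame(label = l,
               region = unname(labelmap$regions[as.character(l)]),
               subregion = unname(labelmap$names[as.character(l)]),
               mean = mean(vals[ok]),
               n_voxels = sum(ok),
               n_excluded = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Exact Wilcoxon rank-sum test
#'
#' Exact two-sided p by full enumeration of all `choose(n_a + n_b, n_a)`
#' assignments of the mid-ranks (ties handled by mid-ranking);
#' `p = min(1, 2 * min(lower tail, upper tail))`. For combined samples
#' larger than 20 a normal approximation with continuity and tie
#' correction is used instead (never reached at this package's study
#' sizes).
#'
#' @param x,y numeric vectors (each of length >= 2)
#' @return an object of class `htest` with the rank-sum statistic of `x`
#'   and the two-sided p-value
#' @export
exact_wilcoxon <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (any(!is.finite(c(x, y)))) stop("values must be finite")
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  eps <- 1e-9
  if (n <= 20L) {
    sums <- colSums(matrix(r[utils::combn(n, nx)], nrow = nx))
    p <- min(1, 2 * min(mean(sums <= W + eps), mean(sums >= W - eps)))
    method <- "Exact Wilcoxon rank-sum test (full enumeration)"
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sig2 <- nx * (n - nx) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  structure(list(statistic = c(W = W), p.value = p, method = method,
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Relative reduction of a group mean
#'
#' `100 * (control - stressed) / control`, the percentage by which the
#' stressed group mean falls below the control mean.
#'
#' @param control_mean,stressed_mean group means; `control_mean` must be
#'   positive
#' @return list with `percent` (full precision), `one_decimal` and
#'   `nearest_integer`
#' @export
relative_reduction <- function(control_mean, stressed_mean) {
  if (!(control_mean > 0)) stop("control mean must be positive")
  pct <- 100 * (control_mean - stressed_mean) / control_mean
  list(percent = pct, one_decimal = round(pct, 1),
       nearest_integer = round(pct))
}

#' Compare stressed and control groups ROI by ROI
#'
#' For each (region, subregion): group mean and sample SD (n - 1
#' denominator) of the subject-level ROI means, exact two-sided Wilcoxon
#' p, relative reduction and a significance flag at `alpha` (uncorrected;
#' an optional Holm adjustment is available behind `holm`).
#'
#' @param summaries data.frame with columns `subject`, `group`
#'   (`"control"`/`"stressed"`), `region`, `subregion`, `mean` — one row
#'   per subject x ROI (as produced by [roi_means()] plus subject/group
#'   columns)
#' @param alpha significance level
#' @param holm apply a Holm correction (off by default)
#' @return data.frame of class `group_comparison`, one row per ROI in the
#'   order of first appearance
#' @export
compare_groups <- function(summaries, alpha = 0.05, holm = FALSE) {
  need <- c("subject", "group", "region", "subregion", "mean")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  key <- paste(summaries$region, summaries$subregion, sep = "\r")
  rois <- unique(key)
  subjects <- unique(summaries$subject)
  tab <- table(summaries$subject, key)
  if (any(tab != 1L))
    stop("every subject needs exactly one summary per ROI")
  rows <- lapply(rois, function(k) {
    sub <- summaries[key == k, ]
    a <- sub$mean[sub$group == "stressed"]
    b <- sub$mean[sub$group == "control"]
    if (length(a) < 2L || length(b) < 2L)
      stop("both a stressed and a control group (>= 2 subjects each) are required")
    ht <- exact_wilcoxon(a, b)
    red <- if (mean(b) > 0) relative_reduction(mean(b), mean(a))$percent
           else NA_real_
    data.frame(region = sub$region[1L], subregion = sub$subregion[1L],
               stressed_mean = mean(a), stressed_sd = stats::sd(a),
               control_mean = mean(b), control_sd = stats::sd(b),
               n_stressed = length(a), n_control = length(b),
               p_value = ht$p.value, reduction_pct = red)
  })
  out <- do.call(rbind, rows)
  if (holm) {
    out$p_holm <- stats::p.adjust(out$p_value, "holm")
    out$significant <- out$p_holm < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Render a group comparison as a plain-text table
#'
#' @param x a [compare_groups()] result
#' @return character vector of table lines
#' @export
format_comparison <- function(x) {
  hdr <- sprintf("%-6s %-9s %-12s %-12s %-7s %-10s %s",
                 "Region", "Subregion", "Stressed", "Control", "P", "Reduction",
                 "")
  lines <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%-6s %-9s %5.2f±%-6.2f %5.2f±%-6.2f %-7.2f %6.1f%%  %s",
            x$region[i], x$subregion[i],
            x$stressed_mean[i], x$stressed_sd[i],
            x$control_mean[i], x$control_sd[i],
            x$p_value[i], x$reduction_pct[i],
            if (isTRUE(x$significant[i])) "*" else "")
  }, character(1))
  c(hdr, lines)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}
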