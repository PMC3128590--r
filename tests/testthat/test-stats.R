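test_that("roi_means summarises labels and excludes sentinels", {
  lay <- default_layers()[1:2, ]
  lm <- make_labelmap(lay, band_width = 5L, n_cols = 2L)
  map <- array(0.4, dim(lm$labels))
  sm <- roi_means(map, lm)
  expect_equal(sm$mean, c(0.4, 0.4))
  expect_equal(sm$n_voxels, c(10L, 10L))
  map2 <- map
  map2[lm$labels == lay$label[1]] <- c(0.2, 0.4)
  sm2 <- roi_means(map2, lm)
  expect_equal(sm2$mean[1], 0.3)
  # NA voxels are excluded and counted
  map3 <- map
  map3[1, 1, 1] <- NA
  sm3 <- roi_means(map3, lm)
  expect_equal(sm3$n_excluded[1], 1L)
  expect_equal(sm3$n_voxels[1], 9L)
  # an all-NA ROI is an error
  map4 <- map
  map4[lm$labels == lay$label[2]] <- NA
  expect_error(roi_means(map4, lm), "no finite voxels")
  expect_error(roi_means(array(0, c(2, 2, 2)), lm), "does not match")
})

test_that("exact Wilcoxon matches full enumeration on the reference cases", {
  w <- exact_wilcoxon(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(w$p.value, 2 / 70)
  expect_equal(unname(w$statistic), 10)
  w2 <- exact_wilcoxon(c(1, 2, 3, 5), c(4, 6, 7, 8))
  expect_equal(w2$p.value, 4 / 70)
  w3 <- exact_wilcoxon(c(1, 1, 1), c(1, 1, 1))
  expect_equal(w3$p.value, 1)
  expect_error(exact_wilcoxon(1, c(1, 2)), "at least 2")
})

test_that("achievable two-sided levels at n = 4/4 are the nine known values", {
  levels_true <- c(2, 4, 8, 14, 24, 34, 48, 62) / 70
  achievable <- sort(unique(vapply(utils::combn(8, 4, simplify = FALSE),
    function(ix) exact_wilcoxon(seq_len(8)[ix], seq_len(8)[-ix])$p.value,
    double(1))))
  expect_equal(achievable, c(levels_true, 1))
  # the printed levels 0.03 / 0.06 / 0.11 / 0.69 are rounded members
  expect_true(all(c(0.03, 0.06, 0.11, 0.69) %in% round(achievable, 2)))
})

test_that("exact test agrees with raw-value permutation at alpha = 0.05", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(4); y <- rnorm(4, 0.8)
    p_rank <- exact_wilcoxon(x, y)$p.value
    # permutation of the raw values: two-sided tail doubling on the
    # group-A sum statistic
    vals <- c(x, y)
    sums <- vapply(utils::combn(8, 4, simplify = FALSE),
                   function(ix) sum(vals[ix]), double(1))
    s_obs <- sum(x)
    p_perm <- min(1, 2 * min(mean(sums <= s_obs + 1e-12),
                             mean(sums >= s_obs - 1e-12)))
    expect_identical(p_rank < 0.05, p_perm < 0.05)
  }
})

test_that("relative reduction reproduces the reference arithmetic", {
  r1 <- relative_reduction(0.39, 0.26)
  expect_equal(r1$one_decimal, 33.3)
  expect_equal(r1$nearest_integer, 33)
  r2 <- relative_reduction(0.31, 0.23)
  expect_equal(r2$one_decimal, 25.8)
  expect_equal(r2$nearest_integer, 26)
  expect_equal(relative_reduction(0.5, 0.5)$percent, 0)
  expect_error(relative_reduction(0, 0.2), "positive")
})

test_that("compare_groups reproduces the reference table structure", {
  lay <- default_layers()
  # zero-variance groups exactly at the reference means
  mk <- function(group, col) do.call(rbind, lapply(1:4, function(i)
    data.frame(subject = paste0(group, i), group = group,
               region = lay$region, subregion = lay$subregion,
               mean = lay[[col]])))
  summ <- rbind(mk("stressed", "stressed_mean"), mk("control", "control_mean"))
  cmp <- compare_groups(summ)
  expect_equal(nrow(cmp), 10L)
  expect_identical(cmp$region, rep(c("CA1", "CA3", "DG"), c(4, 4, 2)))
  # complete separation everywhere the means differ
  expect_true(all(cmp$p_value == 2 / 70))
  expect_true(all(cmp$significant))
  ca3sr <- cmp[cmp$region == "CA3" & cmp$subregion == "SR", ]
  expect_equal(ca3sr$reduction_pct, 100 * (0.43 - 0.33) / 0.43,
               tolerance = 1e-12)
  expect_equal(round(ca3sr$reduction_pct, 1), 23.3)
  # identical groups: p = 1 for every ROI
  summ_same <- rbind(mk("stressed", "control_mean"), mk("control", "control_mean"))
  expect_true(all(compare_groups(summ_same)$p_value == 1))
  # a 4+4 with one crossing subject lands on the 4/70 level
  summ_cross <- summ[summ$region == "CA1" & summ$subregion == "SO", ]
  summ_cross$mean <- c(1, 2, 3, 5, 4, 6, 7, 8)
  expect_equal(compare_groups(summ_cross)$p_value, 4 / 70)
})

test_that("compare_groups validates completeness and supports Holm", {
  lay <- default_layers()[1:2, ]
  summ <- expand.grid(subject = c("s1", "s2", "c1", "c2"),
                      subregion = lay$subregion, stringsAsFactors = FALSE)
  summ$region <- "CA1"
  summ$group <- ifelse(grepl("^s", summ$subject), "stressed", "control")
  summ$mean <- seq(0.2, by = 0.02, length.out = nrow(summ))
  cmp <- compare_groups(summ, holm = TRUE)
  expect_true("p_holm" %in% names(cmp))
  expect_true(all(cmp$p_holm >= cmp$p_value))
  expect_error(compare_groups(summ[-1, ]), "exactly one summary")
  solo <- summ[summ$group == "stressed", ]
  expect_error(compare_groups(solo), "control")
})
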