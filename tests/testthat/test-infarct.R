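# Naive three-class Otsu oracle: bin the values, then for every bin pair
# recompute the class weights and means from scratch and maximize the
# between-class variance directly.
otsu_oracle <- function(values, n_bins) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- hist(values, breaks = edges, plot = FALSE,
                 include.lowest = TRUE, right = TRUE)$counts
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n <- sum(counts)
  mu <- sum(counts * mids) / n
  best <- NULL; best_var <- -Inf
  for (i in 1:(n_bins - 2)) for (j in (i + 1):(n_bins - 1)) {
    idx <- list(1:i, (i + 1):j, (j + 1):n_bins)
    v <- 0
    for (cls in idx) {
      w <- sum(counts[cls]) / n
      if (w > 0) v <- v + w * (sum(counts[cls] * mids[cls]) /
                                 sum(counts[cls]) - mu)^2
    }
    if (v > best_var + 1e-12) { best_var <- v; best <- c(i, j) }
  }
  c(edges[best[1] + 1], edges[best[2] + 1])
}

test_that("Otsu separates three well-separated clusters exactly", {
  x <- c(rep(0, 100), rep(50, 100), rep(100, 100))
  t <- otsu_two_thresholds(x, n_bins = 32)
  expect_true(t[1] > 0 && t[1] < 50)
  expect_true(t[2] >= 50 && t[2] < 100)
  cls <- classify_three(x, t)
  expect_equal(unname(table(cls)), c(100L, 100L, 100L),
               ignore_attr = TRUE)
  expect_error(otsu_two_thresholds(c(1, 1, 2, 2)), "degenerate")
})

test_that("Otsu matches the brute-force oracle on seeded instances", {
  for (s in 1:20) {
    x <- withr::with_seed(s, {
      n <- sample(50:500, 1)
      nb <- sample(c(16, 32, 64), 1)
      modes <- sample(2:4, 1)
      vals <- unlist(lapply(seq_len(modes), function(k)
        rnorm(ceiling(n / modes), mean = 30 * k, sd = runif(1, 1, 8))))
      list(vals = vals, nb = nb)
    })
    got <- otsu_two_thresholds(x$vals, n_bins = x$nb)
    want <- otsu_oracle(x$vals, n_bins = x$nb)
    expect_identical(classify_three(x$vals, got),
                     classify_three(x$vals, want))
  }
})

test_that("Otsu class assignment is invariant under affine rescaling", {
  x <- withr::with_seed(3, rnorm(300, mean = rep(c(10, 40, 90), 100)))
  base <- classify_three(x, otsu_two_thresholds(x, 32))
  for (tr in list(c(2.5, 7), c(0.01, -3))) {
    y <- tr[1] * x + tr[2]
    expect_identical(classify_three(y, otsu_two_thresholds(y, 32)), base)
  }
})

test_that("slice stratification partitions every masked voxel", {
  ph <- make_lv_phantom(noisy_spec(seed = 4,
                                   infarct = list(extent_deg = 90,
                                                  scale = 0)), "rest")
  v <- diastole(ph)
  s <- stratify_slice(v, ph$myocardium_mask, 16)
  expect_equal(sum(s$counts), sum(ph$myocardium_mask$values[, , 16]))
  expect_true(all(!is.na(s$labels[ph$myocardium_mask$values[, , 16]])))
  expect_true(all(is.na(s$labels[!ph$myocardium_mask$values[, , 16]])))
  # all values below the first threshold are labeled low
  s2 <- stratify_slice(v, ph$myocardium_mask, 16,
                       thresholds = c(1e9, 2e9))
  expect_equal(unname(s2$counts[c("medium", "high")]), c(0L, 0L))
  expect_error(stratify_slice(v, ph$myocardium_mask, 1), "intersect")
})

test_that("infarct percentage is low / (low + medium + high)", {
  v <- volume_grid(array(rep(c(1, 5, 9), c(25, 50, 25)), c(10, 10, 1)))
  m <- voi_mask(array(TRUE, c(10, 10, 1)))
  est <- infarct_percentage(v, m, 1, thresholds = c(2, 7))
  expect_equal(unname(est$counts), c(25L, 50L, 25L), ignore_attr = TRUE)
  expect_equal(est$infarct_pct, 25)
  # nothing below the first threshold: 0%
  est0 <- infarct_percentage(v, m, 1, thresholds = c(0.5, 7))
  expect_equal(est0$infarct_pct, 0)
})

test_that("zero-activity wedge voxels are classified as infarct", {
  ph <- make_lv_phantom(noisy_spec(seed = 6,
                                   infarct = list(extent_deg = 90,
                                                  scale = 0)), "rest")
  v <- diastole(ph)
  mid <- 16
  est <- infarct_percentage(v, ph$myocardium_mask, mid)
  m2 <- ph$myocardium_mask$values[, , mid]
  truth <- make_lv_phantom(clean_spec(infarct = list(extent_deg = 90,
                                                     scale = 0)), "rest")
  wedge_pct <- 100 * mean(diastole(truth)$values[, , mid][m2] == 0)
  expect_lt(abs(est$infarct_pct - wedge_pct), 2)
})

test_that("infarct estimate grows with wedge extent at a fixed seed", {
  pcts <- vapply(c(60, 90, 120, 180), function(ext) {
    ph <- make_lv_phantom(noisy_spec(seed = 12,
                                     infarct = list(extent_deg = ext,
                                                    scale = 0)), "rest")
    infarct_percentage(diastole(ph), ph$myocardium_mask, 16)$infarct_pct
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
  expect_true(all(pcts >= 0 & pcts <= 100))
})

test_that("whole-LV aggregate pools per-slice counts", {
  ph <- make_lv_phantom(noisy_spec(seed = 13,
                                   infarct = list(extent_deg = 90,
                                                  scale = 0)), "rest")
  agg <- lv_infarct_summary(diastole(ph), ph$myocardium_mask)
  low <- sum(vapply(agg$per_slice, function(e) e$counts[["low"]],
                    numeric(1)))
  tot <- sum(vapply(agg$per_slice, function(e) sum(e$counts), numeric(1)))
  expect_equal(agg$infarct_pct, 100 * low / tot)
  expect_equal(tot, sum(ph$myocardium_mask$values))
})

test_that("stain segmentation recovers the wedge fraction", {
  ttc <- make_ttc_image(0.25, seed = 2, jitter_sd = 0)
  seg <- stain_infarct(ttc$image)
  ann <- sum(ttc$truth != 0L)
  truth_pct <- 100 * sum(ttc$truth == 2L) / ann
  expect_lt(abs(seg$infarct_pct - truth_pct), 0.5)
  expect_false(any(seg$viable_mask & seg$infarct_mask))
  expect_equal(stain_infarct(make_ttc_image(0, seed = 2)$image)$infarct_pct,
               0)
})

test_that("stain segmentation is invariant to image rotation", {
  ttc <- make_ttc_image(0.3, seed = 7, image_size = 128)
  seg <- stain_infarct(ttc$image)
  rot <- aperm(ttc$image, c(2, 1, 3))[, dim(ttc$image)[1]:1, ]
  seg_rot <- stain_infarct(rot)
  expect_equal(seg_rot$infarct_pct, seg$infarct_pct)
  # a pure-white image has no tissue
  expect_error(stain_infarct(array(1, c(8, 8, 3))), "no tissue")
})
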