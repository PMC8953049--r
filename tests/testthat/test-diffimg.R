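test_that("centroid registration recovers constructed integer shifts", {
  ph <- make_lv_phantom(clean_spec(), "rest")
  v <- diastole(ph); m <- ph$myocardium_mask
  shifted_v <- volume_grid(vascupet:::translate_array(v$values, c(3, 0, -2)),
                           voxel_size_mm = v$voxel_size_mm)
  shifted_m <- voi_mask(vascupet:::translate_array(m$values, c(3, 0, -2),
                                                   fill = FALSE),
                        voxel_size_mm = m$voxel_size_mm)
  reg <- register_rigid(shifted_v, shifted_m, v, m)
  expect_equal(reg$shift, c(-3L, 0L, 2L))
  expect_identical(reg$volume$values, v$values)
  expect_identical(reg$mask$values, m$values)
  # identical inputs: zero shift
  expect_equal(register_rigid(v, m, v, m)$shift, c(0L, 0L, 0L))
  expect_error(register_rigid(v, voi_mask(array(FALSE, dim(v$values))),
                              v, m), "empty")
})

test_that("sub-voxel centroid offsets round to a zero shift", {
  # a mask whose centroid differs by < 0.5 voxel from the reference's
  m1 <- array(FALSE, c(20, 20, 20)); m1[8:12, 8:12, 8:12] <- TRUE
  m2 <- m1
  m2[13, 8:12, 8:12] <- TRUE   # drags the x-centroid by < 0.5 voxel
  v <- volume_grid(array(1, c(20, 20, 20)))
  reg <- register_rigid(v, voi_mask(m2), v, voi_mask(m1))
  expect_equal(reg$shift, c(0L, 0L, 0L))
})

test_that("clipped difference zeroes negatives and respects the mask", {
  d <- c(4, 4, 4)
  stress <- volume_grid(array(5, d))
  rest <- volume_grid(array(3, d))
  mvals <- array(FALSE, d); mvals[1:2, , ] <- TRUE
  m <- voi_mask(mvals)
  out <- clipped_difference(stress, rest, m)
  expect_identical(out$unit, "difference")
  expect_equal(unique(as.vector(out$values[mvals])), 2)
  expect_equal(unique(as.vector(out$values[!mvals])), 0)
  # stress below rest clips to zero; equality gives an all-zero volume
  expect_true(all(clipped_difference(rest, stress, m)$values == 0))
  expect_true(all(clipped_difference(rest, rest, m)$values == 0))
  expect_error(clipped_difference(stress, volume_grid(array(1, c(5, 4, 4))),
                                  m), "geometry error")
})

test_that("clipped sum dominates the raw sum, with equality iff no clipping", {
  withr::with_seed(5, {
    d <- c(6, 6, 6)
    m <- voi_mask(array(TRUE, d))
    stress <- volume_grid(array(runif(216, 0, 10), d))
    rest <- volume_grid(array(runif(216, 0, 10), d))
    clipped <- sum(clipped_difference(stress, rest, m)$values)
    raw <- sum(stress$values - rest$values)
    expect_gt(clipped, raw)   # clipping occurred somewhere
    above <- volume_grid(stress$values + rest$values)
    expect_equal(sum(clipped_difference(above, rest, m)$values),
                 sum(above$values - rest$values))
  })
})

test_that("increased ratio reproduces published row arithmetic", {
  r1 <- vasodilation_result(2496.72, 2008.44, 635.04)
  expect_equal(r1$increased_ratio_pct, 31.62, tolerance = 0.01 / 31.62)
  r3 <- vasodilation_result(18781.97, 15579.75, 3796.07)
  expect_equal(r3$increased_ratio_pct, 24.37, tolerance = 0.01 / 24.37)
  expect_error(vasodilation_result(1, 0, 1), "undefined-ratio")
})

test_that("increased ratio is scale-equivariant and zero at stress = rest", {
  ph <- make_lv_phantom(noisy_spec(seed = 8), "rest")
  v <- diastole(ph); m <- ph$myocardium_mask
  v2 <- volume_grid(v$values * 1.3, v$voxel_size_mm)
  r <- increased_ratio(v2, v, m)
  scaled <- increased_ratio(volume_grid(v2$values * 7, v$voxel_size_mm),
                            volume_grid(v$values * 7, v$voxel_size_mm), m)
  expect_equal(scaled$increased_ratio_pct, r$increased_ratio_pct)
  expect_equal(increased_ratio(v, v, m)$increased_ratio_pct, 0)
})

test_that("noise-free phantoms recover the vasodilation delta exactly", {
  for (d in c(0.2, 0.5, 0.722)) {
    sp <- clean_spec(vasodilation_delta = d)
    rest <- make_lv_phantom(clean_spec(), "rest")
    stress <- make_lv_phantom(sp, "stress")
    r <- increased_ratio(diastole(stress), diastole(rest),
                         rest$myocardium_mask)
    expect_equal(r$increased_ratio_pct, 100 * d)
    brest <- make_brain_phantom(clean_spec(), "rest")
    bstress <- make_brain_phantom(sp, "stress")
    rb <- increased_ratio(bstress$volume, brest$volume, brest$mask)
    expect_equal(rb$increased_ratio_pct, 100 * d)
  }
})

test_that("Poisson-noise recovery stays within 2% relative at high counts", {
  d <- 0.5
  est <- vapply(1:50, function(s) {
    rest <- make_lv_phantom(noisy_spec(seed = s), "rest")
    stress <- make_lv_phantom(noisy_spec(vasodilation_delta = d,
                                         seed = s + 5000), "stress")
    increased_ratio(diastole(stress), diastole(rest),
                    rest$myocardium_mask)$increased_ratio_pct
  }, numeric(1))
  expect_lt(max(abs(est - 100 * d)) / (100 * d), 0.02)
})

test_that("clipping bias is non-negative when counts are low", {
  # ~20 counts per shell voxel: negative fluctuations clip, so the
  # increased-ratio estimator acquires a small positive bias
  d <- 0.2
  est <- vapply(1:50, function(s) {
    rest <- make_lv_phantom(noisy_spec(seed = s, dwell_scale = 0.01),
                            "rest")
    stress <- make_lv_phantom(noisy_spec(vasodilation_delta = d,
                                         seed = s + 5000,
                                         dwell_scale = 0.01), "stress")
    increased_ratio(diastole(stress), diastole(rest),
                    rest$myocardium_mask)$increased_ratio_pct
  }, numeric(1))
  expect_gte(mean(est) - 100 * d, 0)
})
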