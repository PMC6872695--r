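const_phantom <- function(value = 4, dims = c(7, 7, 7),
                          spacing = c(2, 2, 2)) {
  vox <- array(value, dim = dims)
  mask <- array(FALSE, dim = dims)
  mask[2:6, 2:6, 2:6] <- TRUE
  list(volume = suv_volume(vox, spacing), mask = roi_mask(mask, spacing))
}

test_that("SUVmax and SUVmean match exhaustive masked scans", {
  ph <- const_phantom(4)
  expect_equal(suv_max(ph$volume, ph$mask), 4)
  hot <- ph$volume
  hot$voxels[3, 3, 3] <- 9.3
  hot$voxels[1, 1, 1] <- 50     # outside the mask, must be ignored
  expect_equal(suv_max(hot, ph$mask), 9.3)
  withr::with_seed(11, {
    for (i in 1:20) {
      ph <- random_test_phantom()
      expect_equal(suv_max(ph$volume, ph$mask),
                   max(ph$volume$voxels[ph$mask$voxels]))
      expect_equal(suv_mean(ph$volume, ph$mask),
                   mean(ph$volume$voxels[ph$mask$voxels]))
    }
  })
})

test_that("SUVpeak averages a 1 cm3 sphere at the hottest voxel", {
  ph <- const_phantom(4)
  expect_equal(suv_peak(ph$volume, ph$mask), 4)
  # single hot voxel in uniform background: mean = (hot + (k-1)*bg) / k
  vol <- suv_volume(array(2, dim = c(9, 9, 9)), spacing = c(2, 2, 2))
  vol$voxels[5, 5, 5] <- 9.3
  mask <- roi_mask(vol$voxels > 0, spacing = c(2, 2, 2))
  # independent geometric enumeration of voxel centers in the sphere
  grid <- expand.grid(i = 1:9, j = 1:9, k = 1:9)
  d2 <- (2 * (grid$i - 5))^2 + (2 * (grid$j - 5))^2 + (2 * (grid$k - 5))^2
  k_in <- sum(d2 <= 6.2035^2)
  expect_equal(suv_peak(vol, mask), (9.3 + (k_in - 1) * 2) / k_in)
})

test_that("SUVpeak never exceeds SUVmax", {
  withr::with_seed(12, {
    for (i in 1:50) {
      ph <- random_test_phantom(dims = c(10, 9, 8))
      expect_lte(suv_peak(ph$volume, ph$mask), suv_max(ph$volume, ph$mask))
    }
  })
})

test_that("MTV is voxel count times voxel volume in mL", {
  arr <- array(FALSE, dim = c(10, 10, 10))
  arr[1:4, 1:5, 1:5] <- TRUE   # 100 voxels
  m <- roi_mask(arr, spacing = c(4.7, 4.7, 3.3))
  expect_equal(mtv(m), 100 * 4.7 * 4.7 * 3.3 / 1000)
  expect_equal(mtv(m), 7.2897)
  one <- array(FALSE, dim = c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(mtv(roi_mask(one, spacing = c(10, 10, 10))), 1.0)
})

test_that("TLG is exactly SUVmean x MTV and matches direct summation", {
  ph <- const_phantom(5, spacing = c(2, 2, 5))
  expect_identical(tlg(ph$volume, ph$mask),
                   suv_mean(ph$volume, ph$mask) * mtv(ph$mask))
  withr::with_seed(13, {
    for (i in 1:20) {
      ph <- random_test_phantom(spacing = c(2, 2, 3.3))
      expect_identical(tlg(ph$volume, ph$mask),
                       suv_mean(ph$volume, ph$mask) * mtv(ph$mask))
      # equivalent voxelwise summation oracle
      direct <- sum(ph$volume$voxels[ph$mask$voxels]) *
        prod(ph$volume$spacing) / 1000 / sum(ph$mask$voxels) *
        sum(ph$mask$voxels)
      expect_equal(tlg(ph$volume, ph$mask), direct, tolerance = 1e-12)
    }
  })
})

test_that("histogram entropy reproduces analytic cases", {
  # constant ROI: one occupied bin, entropy numerically zero
  ph <- const_phantom(4)
  expect_lt(abs(histogram_entropy(ph$volume, ph$mask)), 1e-12)
  # 8 voxels split 4/4 across two bins: 1 bit
  vox <- array(1, dim = c(2, 2, 2)); vox[1:4] <- 2
  vol <- suv_volume(vox, spacing = c(2, 2, 2))
  mask <- roi_mask(array(TRUE, dim = c(2, 2, 2)), spacing = c(2, 2, 2))
  expect_equal(histogram_entropy(vol, mask, n_bins = 2), 1.0,
               tolerance = 1e-9)
  # all 64 bins equally occupied: log2(64) bits
  centers <- seq(0.5, 63.5, by = 1) / 64 * 10 + 2
  vox64 <- array(centers, dim = c(4, 4, 4))
  vol64 <- suv_volume(vox64, spacing = c(2, 2, 2))
  mask64 <- roi_mask(array(TRUE, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
  expect_equal(histogram_entropy(vol64, mask64, n_bins = 64), log2(64),
               tolerance = 1e-6)
  expect_lte(histogram_entropy(vol64, mask64, n_bins = 64),
             log2(64) + 1e-12)
})

test_that("entropy and COV are distribution statistics", {
  withr::with_seed(14, {
    ph <- random_test_phantom(dims = c(9, 9, 9))
    e0 <- histogram_entropy(ph$volume, ph$mask)
    c0 <- suv_cov(ph$volume, ph$mask)
    # spatial permutation of the masked values changes nothing
    perm <- ph$volume
    vals <- perm$voxels[ph$mask$voxels]
    perm$voxels[ph$mask$voxels] <- sample(vals)
    expect_equal(histogram_entropy(perm, ph$mask), e0, tolerance = 1e-12)
    expect_equal(suv_cov(perm, ph$mask), c0, tolerance = 1e-12)
    # positive rescaling changes nothing (min-max bins rescale too)
    scaled <- ph$volume
    scaled$voxels <- scaled$voxels * 3.2
    expect_equal(histogram_entropy(scaled, ph$mask), e0, tolerance = 1e-9)
    expect_equal(suv_cov(scaled, ph$mask), c0, tolerance = 1e-12)
  })
})

test_that("absolute-bound binning scores narrow uptake low", {
  dims <- c(6, 6, 6)
  mask <- roi_mask(array(TRUE, dims), spacing = c(2, 2, 2))
  withr::with_seed(15, {
    narrow <- suv_volume(array(rnorm(216, 8, 0.05), dims), c(2, 2, 2))
    wide <- suv_volume(array(runif(216, 2, 20), dims), c(2, 2, 2))
  })
  e_narrow <- histogram_entropy(narrow, mask, bin_range = c(0, 25))
  e_wide <- histogram_entropy(wide, mask, bin_range = c(0, 25))
  expect_lt(e_narrow, e_wide)
  expect_lt(e_narrow, 2)
})

test_that("COV follows the population-SD convention", {
  ph <- const_phantom(4)
  expect_equal(suv_cov(ph$volume, ph$mask), 0)
  vox <- array(c(1, 3), dim = c(2, 1, 1))
  vol <- suv_volume(vox, spacing = c(5, 5, 5))
  mask <- roi_mask(array(TRUE, dim = c(2, 1, 1)), spacing = c(5, 5, 5))
  expect_equal(suv_cov(vol, mask), 0.5)                 # pop SD 1, mean 2
  expect_equal(suv_cov(vol, mask, type = "sample"), sqrt(2) / 2)
  scaled <- vol; scaled$voxels <- scaled$voxels * 7
  expect_equal(suv_cov(scaled, mask), 0.5, tolerance = 1e-12)
})

test_that("extract_pet_features composes the individual operations", {
  withr::with_seed(16, {
    for (i in 1:10) {
      ph <- random_test_phantom(dims = c(9, 8, 8))
      f <- extract_pet_features(ph$volume, ph$mask, resample = FALSE)
      expect_equal(f$suv_max, suv_max(ph$volume, ph$mask))
      expect_equal(f$suv_peak, suv_peak(ph$volume, ph$mask))
      expect_equal(f$suv_mean, suv_mean(ph$volume, ph$mask))
      expect_equal(f$mtv_ml, mtv(ph$mask))
      expect_identical(f$tlg, f$suv_mean * f$mtv_ml)
      expect_equal(f$entropy_bits, histogram_entropy(ph$volume, ph$mask))
      expect_equal(f$cov, suv_cov(ph$volume, ph$mask))
      expect_lte(f$suv_peak, f$suv_max)
      expect_gte(f$cov, 0)
    }
  })
})

test_that("features stay finite for the smallest tumors after resampling", {
  # 0.36 mL tumor on a fine grid, extracted at a 2 mm analysis grid
  withr::with_seed(17, {
    ph <- gen_phantom(0.8, 0.36)
  })
  f <- extract_pet_features(ph$volume, ph$mask, target_spacing = c(2, 2, 2))
  expect_true(all(vapply(f, is.finite, logical(1))))
  expect_gt(f$mtv_ml, 0)
})
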