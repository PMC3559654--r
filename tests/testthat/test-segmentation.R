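test_that("axial cropping preserves the selected slices and zeroes the rest", {
  ph <- cached_phantom()$ph
  truth <- ph$truth
  nz <- dim(truth$labels)[3]

  expect_identical(crop_axial_extent(truth, c(1, nz))$labels, truth$labels)

  k <- ph$z_range[1] + 3L
  one <- crop_axial_extent(truth, c(k, k))
  expect_equal(sum(one$labels != 0), sum(truth$labels[, , k] != 0))

  half <- c(ph$z_range[1], ph$z_range[1] + diff(ph$z_range) %/% 2)
  cropped <- crop_axial_extent(truth, half)
  in_range <- truth$labels[, , half[1]:half[2]]
  expect_equal(sum(cropped$labels == TISSUE_CODES[["muscle"]]),
               sum(in_range == TISSUE_CODES[["muscle"]]))

  expect_error(crop_axial_extent(truth, c(5, 2)), "ordered")
  expect_error(crop_axial_extent(truth, c(0, 4)), "outside")
  expect_error(crop_axial_extent(truth, c(1, nz + 1)), "outside")
})

test_that("segmentation recovers the phantom tissues at the study SNRs", {
  cp <- cached_phantom()
  truth <- consolidate_truth(cp$ph$truth)
  for (cl in c("muscle", "subcut_fat", "tibia", "fibula"))
    expect_gte(dice(cp$seg, truth, cl), 0.95)

  # noiseless phantom: essentially exact
  ph0 <- generate_leg_phantom(small_spec(snr_fat = Inf, snr_muscle = Inf,
                                         seed = 5))
  seg0 <- segment_tissues(ph0$grid)
  truth0 <- consolidate_truth(ph0$truth)
  for (cl in c("muscle", "subcut_fat", "tibia", "fibula"))
    expect_gte(dice(seg0, truth0, cl), 0.99)
})

test_that("segmentation output is a partition and conserves voxels", {
  cp <- cached_phantom()
  expect_equal(sum(table(cp$seg$labels)), prod(dim(cp$seg$labels)))
  expect_true(all(unique(as.vector(cp$seg$labels)) %in%
                    TISSUE_CODES[c("background", "muscle", "subcut_fat",
                                   "tibia", "fibula")]))
})

test_that("a constant image raises a degenerate-image error", {
  flat <- voxel_grid(array(100, c(16, 16, 8)))
  expect_error(segment_tissues(flat), "degenerate")
})

test_that("fixed thresholds drive the same pipeline", {
  cp <- cached_phantom()
  seg <- segment_tissues(cp$ph$grid,
                         segmentation_config(threshold_mode = "fixed",
                                             fixed_thresholds = c(50, 200)))
  truth <- consolidate_truth(cp$ph$truth)
  expect_gte(dice(seg, truth, "muscle"), 0.95)
  expect_error(segmentation_config(threshold_mode = "fixed",
                                   fixed_thresholds = c(200, 50)),
               "increasing")
})

test_that("raising the small-object threshold never increases component counts", {
  # a noisy phantom so that misclassified specks actually occur
  ph <- generate_leg_phantom(small_spec(snr_fat = 3, snr_muscle = 3, seed = 2,
                                        speckle_fraction = 0))
  n_comps <- function(min_vox) {
    seg <- segment_tissues(ph$grid, segmentation_config(
      min_component_voxels = min_vox))
    vapply(c("muscle", "subcut_fat"), function(cl) {
      mask <- seg$labels == TISSUE_CODES[[cl]]
      max(legquant:::.cc_label_3d(as.vector(mask), dim(mask), 6L))
    }, numeric(1))
  }
  counts <- vapply(c(1, 27, 125), n_comps, numeric(2))
  expect_true(all(diff(t(counts))[, 1] <= 0))
  expect_true(all(diff(t(counts))[, 2] <= 0))
})

test_that("angiography subtraction checks alignment and subtracts voxelwise", {
  a <- voxel_grid(array(rnorm(512), c(8, 8, 8)))
  expect_equal(mra_subtract(a, a)$values, array(0, c(8, 8, 8)))
  b <- voxel_grid(array(0, c(8, 8, 4)))
  expect_error(mra_subtract(a, b), "aligned")
  b2 <- voxel_grid(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_error(mra_subtract(a, b2), "aligned")
})

test_that("artery segmentation recovers the vessel from the difference image", {
  pair <- generate_mra_pair(small_spec(speckle_fraction = 0,
                                       artery_radius_mm = 3, seed = 13))
  d <- mra_subtract(pair$systolic, pair$diastolic)
  seg <- segment_arteries(d, threshold_sd_mult = 5)
  expect_gte(dice(seg, pair$artery_truth, "artery"), 0.8)

  # zero difference image -> no arteries
  zero <- voxel_grid(array(0, c(8, 8, 8)))
  expect_equal(sum(segment_arteries(zero)$labels), 0)

  # threshold 0 keeps every voxel at or above the (zero) threshold before
  # cleanup: all truth artery voxels and roughly half of the noise
  raw <- segment_arteries(d, threshold_sd_mult = 0, min_component_voxels = 1)
  art <- pair$artery_truth$labels == TISSUE_CODES[["artery"]]
  expect_gte(mean(raw$labels[art] > 0), 0.99)
  expect_gt(mean(raw$labels > 0), 0.4)
})
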