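test_that("phantom generation is deterministic and label map is a partition", {
  spec <- small_spec(seed = 21)
  a <- generate_leg_phantom(spec)
  b <- generate_leg_phantom(spec)
  expect_identical(a$grid$values, b$grid$values)
  expect_identical(a$truth$labels, b$truth$labels)

  counts <- table(a$truth$labels)
  expect_equal(sum(counts), prod(spec$grid_shape))
  expect_true(all(as.integer(names(counts)) %in% TISSUE_CODES))
})

test_that("realized tissue volumes track the requested targets within 2%", {
  set.seed(101)
  for (i in 1:6) {
    tv <- c(muscle = runif(1, 150, 280), subcut_fat = runif(1, 90, 200),
            tibia = runif(1, 30, 60), fibula = runif(1, 6, 14))
    spec <- phantom_spec(grid_shape = c(64, 64, 48), voxel_size = c(2, 2, 3),
                         leg_length_mm = 120, target_volumes = tv,
                         speckle_fraction = runif(1, 0, 0.1),
                         artery_radius_mm = sample(c(0, 2.5), 1),
                         seed = i)
    rv <- realized_volumes(generate_leg_phantom(spec)$truth)
    expect_lt(abs(rv[["muscle"]] + rv[["intramuscular_fat"]] -
                    tv[["muscle"]]) / tv[["muscle"]], 0.02)
    for (tis in c("subcut_fat", "tibia", "fibula"))
      expect_lt(abs(rv[[tis]] - tv[[tis]]) / tv[[tis]], 0.02)
  }
})

test_that("zero speckle fraction gives no intramuscular-fat voxels", {
  ph <- generate_leg_phantom(small_spec(speckle_fraction = 0, seed = 4))
  expect_equal(sum(ph$truth$labels == TISSUE_CODES[["intramuscular_fat"]]), 0)
})

test_that("noiseless class means honour the Michelson contrasts", {
  spec <- small_spec(snr_fat = Inf, snr_muscle = Inf, seed = 9)
  ph <- generate_leg_phantom(spec)
  v <- ph$grid$values; lab <- ph$truth$labels
  m_musc <- mean(v[lab == TISSUE_CODES[["muscle"]]])
  m_fat <- mean(v[lab == TISSUE_CODES[["subcut_fat"]]])
  m_bone <- mean(v[lab == TISSUE_CODES[["tibia"]]])
  expect_lt(abs((m_fat - m_musc) / (m_fat + m_musc) - 0.52), 0.05)
  expect_lt(abs((m_musc - m_bone) / (m_musc + m_bone) - 0.75), 0.05)
})

test_that("per-class noise levels follow the configured SNRs", {
  ph <- generate_leg_phantom(small_spec(seed = 30))
  v <- ph$grid$values; lab <- ph$truth$labels
  musc <- v[lab == TISSUE_CODES[["muscle"]]]
  fat <- v[lab == TISSUE_CODES[["subcut_fat"]]]
  expect_lt(abs(sd(musc) / (mean(musc) / 57) - 1), 0.05)
  expect_lt(abs(sd(fat) / (mean(fat) / 180) - 1), 0.05)
})

test_that("geometrically infeasible targets fail naming the tissue", {
  expect_error(
    phantom_spec(grid_shape = c(32, 32, 24), voxel_size = c(1, 1, 1),
                 leg_length_mm = 20,
                 target_volumes = c(muscle = 220, subcut_fat = 150,
                                    tibia = 48, fibula = 9)),
    "infeasible.*muscle")
  expect_error(small_spec(speckle_fraction = 0.7), "speckle_fraction")
  expect_error(small_spec(snr_fat = 0.5), "SNR")
  expect_error(small_spec(contrast_fat_muscle = 1.2), "contrast")
})

test_that("cohort generator applies and records ground-truth multipliers", {
  base <- tiny_spec()
  # zero-variance draw: affected target exactly 0.6 x unaffected
  cs <- cohort_spec(n_control = 0, n_unilateral = 1, n_bilateral = 0,
                    effect_ratios = list(muscle = c(0.6, 0),
                                         subcut_fat = c(1.05, 0),
                                         tibia = c(0.92, 0),
                                         fibula = c(0.89, 0)),
                    seed = 11)
  coh <- generate_unilateral_cohort(cs, base)
  legs <- coh$participants$U1$legs
  expect_equal(legs$affected$target_volumes[["muscle"]],
               0.6 * legs$unaffected$target_volumes[["muscle"]])
  expect_equal(coh$truth$multiplier[coh$truth$tissue == "muscle"], 0.6)

  # stochastic draws: recorded sample mean near the distribution mean
  cs2 <- cohort_spec(n_control = 0, n_unilateral = 4, n_bilateral = 0,
                     seed = 42)
  coh2 <- generate_unilateral_cohort(cs2, base)
  drawn <- coh2$truth$multiplier[coh2$truth$tissue == "muscle"]
  expect_length(drawn, 4)
  expect_lt(abs(mean(drawn) - 0.6), 3 * 0.078 / sqrt(4))

  # control multipliers hug 1
  cs3 <- cohort_spec(n_control = 5, n_unilateral = 0, n_bilateral = 0,
                     control_ratios = list(muscle = c(1, 0.03),
                                           subcut_fat = c(1, 0.03),
                                           tibia = c(1, 0.03),
                                           fibula = c(1, 0.03)),
                     seed = 1)
  coh3 <- generate_unilateral_cohort(cs3, base)
  expect_true(all(coh3$truth$multiplier > 0.9 & coh3$truth$multiplier < 1.1))

  # determinism
  coh2b <- generate_unilateral_cohort(cs2, base)
  expect_identical(coh2$truth, coh2b$truth)
})

test_that("systole/diastole pairs differ only at the artery plus noise", {
  spec <- small_spec(speckle_fraction = 0, artery_radius_mm = 3, seed = 13)
  pair <- generate_mra_pair(spec)
  d <- mra_subtract(pair$systolic, pair$diastolic)
  art <- pair$artery_truth$labels == TISSUE_CODES[["artery"]]
  noise_sd <- sd(d$values[!art])
  expect_gt(mean(d$values[art] > 5 * noise_sd), 0.95)
  expect_lt(abs(mean(d$values[!art])), 3 * noise_sd / sqrt(sum(!art)) * 5)

  # no artery: difference is pure zero-mean noise
  pair0 <- generate_mra_pair(small_spec(artery_radius_mm = 0, seed = 13))
  d0 <- mra_subtract(pair0$systolic, pair0$diastolic)
  expect_lt(abs(mean(d0$values)), 0.05)
  expect_equal(sum(pair0$artery_truth$labels), 0)

  # determinism
  pair_b <- generate_mra_pair(spec)
  expect_identical(pair$systolic$values, pair_b$systolic$values)
  expect_identical(pair$diastolic$values, pair_b$diastolic$values)
})
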