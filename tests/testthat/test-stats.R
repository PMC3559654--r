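test_that("summary statistics use the sample-SD convention", {
  s <- summarize_values(c(100, 102, 98))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 2)
  expect_equal(s$n, 3)
  expect_true(s$q1 <= s$median && s$median <= s$q3)

  one <- summarize_values(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_error(summarize_values(numeric(0)), "empty sample")
})

test_that("per-participant averaging pools bilateral legs and passes unilateral through", {
  df <- data.frame(
    participant = c("B1", "B1", "U1", "U1", "C1", "C1"),
    group = c("bilateral", "bilateral", "unilateral", "unilateral",
              "control", "control"),
    side_status = c("right", "left", "affected", "unaffected",
                    "right", "left"),
    value = c(20.3, 14.5, 36.9, 50.9, 62.3, 62.6))
  out <- per_participant_affected_average(df)
  expect_equal(out[["B1"]], 17.4)
  expect_equal(out[["U1"]], 36.9)
  expect_false("C1" %in% names(out))

  incomplete <- df[-4, ]
  incomplete$side_status[3] <- "unaffected"
  expect_error(per_participant_affected_average(incomplete), "incomplete")
})

test_that("exact KS p-values match brute-force enumeration, ties included", {
  set.seed(205)
  for (i in 1:25) {
    n <- sample(2:7, 1); m <- sample(2:6, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, m, replace = TRUE) + sample(c(0, 0.5), m, replace = TRUE)
    res <- ks_two_sample(x, y, method = "exact")
    oracle <- brute_force_ks(x, y)
    expect_equal(res$D, oracle$D)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("KS edge cases: identity, full separation, monotonicity, invariance", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3), method = "exact")
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  sep <- ks_two_sample(1:10, 11:16, method = "exact")
  expect_equal(sep$D, 1)
  expect_equal(sep$p_value, 2 / choose(16, 6))

  # D is invariant under strictly monotone transforms of both samples
  set.seed(8)
  x <- rnorm(7); y <- rnorm(9, 1)
  d1 <- ks_two_sample(x, y, method = "exact")$D
  d2 <- ks_two_sample(exp(x), exp(y), method = "exact")$D
  expect_equal(d1, d2)

  # p decreases weakly as D increases at fixed n, m
  set.seed(14)
  res <- lapply(1:12, function(i)
    ks_two_sample(rnorm(5), rnorm(6, runif(1, 0, 3)), method = "exact"))
  Ds <- vapply(res, `[[`, numeric(1), "D")
  ps <- vapply(res, `[[`, numeric(1), "p_value")
  ord <- order(Ds)
  expect_true(all(diff(ps[ord]) <= 1e-12))

  expect_error(ks_two_sample(numeric(0), 1:3), "empty sample")
  expect_error(ks_two_sample(1:20, 1:20, method = "exact",
                             exact_limit = 30), "exact method limited")
})

test_that("permutation and asymptotic methods approximate the exact null", {
  set.seed(31)
  x <- rnorm(8); y <- rnorm(7, 0.8)
  ex <- ks_two_sample(x, y, method = "exact")
  pm <- ks_two_sample(x, y, method = "permutation", n_perm = 4000, seed = 2)
  expect_equal(pm$D, ex$D)
  expect_lt(abs(pm$p_value - ex$p_value), 0.02)
  as <- ks_two_sample(rnorm(60), rnorm(55, 1), method = "asymptotic")
  expect_true(as$p_value > 0 && as$p_value <= 1)
  expect_lt(as$p_value, 0.01)
})

test_that("the exact engine agrees with the reference implementation on untied data", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    ours <- ks_two_sample(x, y, method = "exact")$p_value
    ref <- suppressWarnings(stats::ks.test(x, y, exact = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("FEM is the cross-operator coefficient of variation", {
  expect_equal(fem(c(7, 7, 7)), 0)
  expect_equal(fem(c(100, 102, 98)), 2)
  expect_error(fem(5), "insufficient replicates")
  expect_error(fem(c(1, -1)), "> 0")
})

test_that("replicated segmentations of one phantom have muscle FEM below 4%", {
  ph <- cached_phantom()$ph
  # three operators emulated by perturbed threshold choices
  base_thr <- legquant:::otsu_two_thresholds(as.vector(ph$grid$values))
  vols <- vapply(c(0.93, 1, 1.07), function(sc) {
    seg <- segment_tissues(ph$grid, segmentation_config(
      threshold_mode = "fixed", fixed_thresholds = base_thr * sc))
    volume_from_labels(seg, "muscle")
  }, numeric(1))
  expect_lt(fem(vols), 4)
})
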