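test_that("the fixture pipeline reproduces the published group statistics", {
  rep <- run_pipeline(load_paper_fixture())

  expect_equal(rep$contrasts$V_Leg_ratio$D, 1)
  expect_equal(rep$contrasts$V_Musc_ratio$D, 1)
  expect_equal(rep$contrasts$V_Tibia_ratio$D, 1)
  expect_equal(rep$contrasts$V_Fibula_ratio$D, 1)
  expect_equal(rep$contrasts$V_Fat_ratio$D, 0.6)
  expect_equal(rep$contrasts$muscle_pct$D, 0.8)
  expect_equal(rep$contrasts$ta_musc$D, 1)
  # the fully separated 10-vs-6 contrast has the standard exact p-value
  expect_equal(rep$contrasts$ta_musc$p_value, 2 / choose(16, 6))

  s <- rep$summaries
  expect_equal(round(s$unaffected_muscle_pct$mean, 1), 58.8)
  expect_equal(round(s$control_muscle_pct$mean), 60)
  expect_equal(round(s$affected_ta_musc$mean, 1), 7.2)
  expect_equal(s$control_V_Leg_ratio$n, 5)
  expect_equal(s$unilateral_V_Leg_ratio$n, 4)
  expect_equal(s$affected_muscle_pct$n, 6)
})

test_that("the image pipeline is deterministic and oriented correctly", {
  base <- tiny_spec(speckle_fraction = 0.015)
  cs <- cohort_spec(n_control = 1, n_unilateral = 1, n_bilateral = 1,
                    seed = 23)
  coh <- generate_unilateral_cohort(cs, base)
  r1 <- run_pipeline(coh)
  r2 <- run_pipeline(generate_unilateral_cohort(cs, base))
  expect_identical(r1$leg_table, r2$leg_table)
  expect_identical(r1$ratio_table, r2$ratio_table)

  rt <- r1$ratio_table
  expect_equal(rt$orientation[rt$group == "unilateral"],
               "affected:unaffected")
  expect_equal(rt$orientation[rt$group == "control"], "right:left")
  # the affected leg's muscle ratio tracks the drawn truth multiplier
  truth_m <- coh$truth$multiplier[coh$truth$tissue == "muscle" &
                                    coh$truth$group == "unilateral"]
  expect_lt(abs(rt$V_Musc_ratio[rt$group == "unilateral"] - truth_m), 0.05)
  # the unilateral affected leg carries enriched intramuscular fat
  expect_gt(rt$TA_Musc_ratio[rt$group == "unilateral"], 2)
})

test_that("zero-effect cohorts rarely produce significant contrasts", {
  base <- tiny_spec()
  null_ratios <- lapply(c("muscle", "subcut_fat", "tibia", "fibula"),
                        function(x) c(1, 0.03))
  names(null_ratios) <- c("muscle", "subcut_fat", "tibia", "fibula")
  n_sig <- 0
  for (r in 1:20) {
    cs <- cohort_spec(n_control = 5, n_unilateral = 4, n_bilateral = 0,
                      effect_ratios = null_ratios,
                      ta_affected_multiplier = 1, seed = 100 + r)
    rep <- run_pipeline(generate_unilateral_cohort(cs, base))
    ks <- rep$contrasts[c("V_Leg_ratio", "V_Musc_ratio", "V_Fat_ratio",
                          "V_Tibia_ratio", "V_Fibula_ratio")]
    sig <- any(vapply(ks, function(k) k$D >= 1 || k$p_value <= 0.05,
                      logical(1)))
    n_sig <- n_sig + sig
  }
  expect_lte(n_sig, 2)   # at most 10% of replicates
})

test_that("recovery of null and fixed effects through the image pipeline", {
  base <- tiny_spec()
  exact <- list(muscle = c(0.6, 0), subcut_fat = c(1.05, 0),
                tibia = c(0.92, 0), fibula = c(0.89, 0))
  pr <- parameter_recovery(cohort_spec(n_control = 0, n_unilateral = 2,
                                       n_bilateral = 0,
                                       effect_ratios = exact, seed = 6),
                           base, n_replicates = 1)
  expect_equal(pr$mean_truth,
               c(0.6, 1.05, 0.92, 0.89)[match(pr$tissue,
                 c("muscle", "subcut_fat", "tibia", "fibula"))])
  expect_true(all(abs(pr$bias) < 0.06))
})

test_that("rendered tables reproduce published cells with report rounding", {
  rep <- run_pipeline(load_paper_fixture())
  dir <- tempfile()
  paths <- render_tables(rep, dir)
  expect_true(all(file.exists(paths)))

  soft <- read.csv(paths[["soft_tissue"]])
  expect_equal(soft$Muscle_pct[soft$participant == "C1" &
                                 soft$side == "right"], 62.3)
  bones <- read.csv(paths[["bone_volumes"]])
  expect_equal(unique(bones$V_Tibia_ratio[bones$participant == "U3"]), 0.85)
  leg <- read.csv(paths[["leg_volumes"]])
  expect_equal(unique(leg$V_Leg_ratio[leg$participant == "U3"]), 0.72)

  # an empty report still writes headers
  empty <- structure(list(leg_table = rep$leg_table[0, ],
                          ratio_table = rep$ratio_table[0, ],
                          summaries = list(), contrasts = list()),
                     class = "cohort_report")
  dir2 <- tempfile()
  p2 <- render_tables(empty, dir2)
  expect_true(all(file.exists(p2)))
  expect_equal(nrow(read.csv(p2[["soft_tissue"]])), 0)
})

test_that("incomplete cohorts are rejected", {
  tab <- load_paper_fixture()
  expect_error(run_pipeline(tab[tab$side == "right" |
                                  tab$participant != "C1", ]),
               "incomplete")
})
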