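test_that("cohort generation honors sizes, labels, and determinism", {
  cfg <- cohort_config(seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 160L)
  expect_equal(sum(cohort$group == 1), 80L)
  expect_equal(sum(cohort$group == -1), 80L)

  tiny <- generate_cohort(cohort_config(n_per_group = 2, seed = 5))
  expect_equal(tiny$group, c(1L, 1L, -1L, -1L))

  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(cohort_config(seed = 2))))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(effect_fraction = 1.2), "effect_fraction")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(age_range = c(57, 18)), "age_range")
  expect_error(cohort_config(metric_name = "MD"))
})

test_that("groups are age-matched and covariates follow the cohort design", {
  for (seed in 1:5) {
    cohort <- generate_cohort(cohort_config(n_per_group = 40, seed = seed))
    a1 <- cohort$age[cohort$group == 1]
    a2 <- cohort$age[cohort$group == -1]
    se <- sd(a1) / sqrt(length(a1))
    expect_lt(abs(mean(a1) - mean(a2)), 0.5 * se)
    expect_true(all(cohort$age >= 18 & cohort$age <= 57))
  }
  cohort <- generate_cohort(cohort_config(seed = 3))
  expect_true(all(cohort$ptsd %in% 1:3))
  tbi <- cohort$group == 1
  expect_true(all(!is.na(cohort$n_tbis[tbi])))
  expect_true(all(is.na(cohort$n_tbis[!tbi])))
  expect_true(all(cohort$years_since_last_tbi[tbi] <=
                    cohort$years_since_first_tbi[tbi]))
  expect_true(all(cohort$n_tbis[tbi] >= 1))
})

test_that("metric stacks follow the generative model", {
  # null data: no affected voxels
  cfg0 <- cohort_config(n_per_group = 5, n_voxels = 50, effect_fraction = 0,
                        seed = 2)
  sim0 <- simulate_dataset(cfg0)
  expect_length(sim0$truth$affected, 0)
  expect_true(all(sim0$truth$shift == 0))

  # near-noiseless limit: affected-voxel group means differ by ~ d * sigma,
  # with the FA effect directed downward in the TBI+ group
  cfg <- cohort_config(n_per_group = 50, n_voxels = 200, effect_fraction = 0.25,
                       effect_size = 3, noise_sd = 1e-3, age_slope = 0,
                       seed = 4)
  sim <- simulate_dataset(cfg)
  expect_length(sim$truth$affected, 50L)
  g1 <- sim$cohort$group == 1
  diffs <- colMeans(sim$stack$values[g1, sim$truth$affected, drop = FALSE]) -
    colMeans(sim$stack$values[!g1, sim$truth$affected, drop = FALSE])
  expect_equal(mean(diffs), -3e-3, tolerance = 0.05)
  un <- setdiff(seq_len(200), sim$truth$affected)
  diffs_un <- colMeans(sim$stack$values[g1, un, drop = FALSE]) -
    colMeans(sim$stack$values[!g1, un, drop = FALSE])
  expect_lt(abs(mean(diffs_un)), 5e-4)

  # ODI effect is directed upward by default
  cfgo <- cohort_config(n_per_group = 50, n_voxels = 100, effect_fraction = 0.5,
                        effect_size = 3, noise_sd = 1e-3, age_slope = 0,
                        metric_name = "ODI", seed = 4)
  simo <- simulate_dataset(cfgo)
  expect_true(all(simo$truth$shift[simo$truth$affected] > 0))

  # stacks are deterministic and clipped to [0, 1] even under heavy noise
  expect_identical(generate_metric_stack(sim$cohort, cfg),
                   generate_metric_stack(sim$cohort, cfg))
  wild <- simulate_dataset(cohort_config(n_per_group = 5, n_voxels = 100,
                                         noise_sd = 0.8, seed = 6))
  expect_true(all(wild$stack$values >= 0 & wild$stack$values <= 1))
})

test_that("null stacks give centrally t-distributed voxelwise statistics", {
  cfg <- cohort_config(n_per_group = 20, n_voxels = 2500, effect_fraction = 0,
                       age_slope = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  tv <- voxelwise_t(sim$stack, sim$cohort$group)
  ks <- suppressWarnings(stats::ks.test(tv$t, stats::pt, df = tv$df))
  expect_gt(ks$p.value, 0.01)
})

test_that("affected voxels carry systematically larger |t| than unaffected", {
  for (seed in 1:20) {
    cfg <- cohort_config(n_per_group = 20, n_voxels = 500,
                         effect_fraction = 0.1, effect_size = 1.5, seed = seed)
    sim <- simulate_dataset(cfg)
    tv <- voxelwise_t(sim$stack, sim$cohort$group)
    aff <- sim$truth$affected
    expect_gt(mean(abs(tv$t[aff])), mean(abs(tv$t[-aff])))
  }
})
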