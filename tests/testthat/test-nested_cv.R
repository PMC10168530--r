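test_that("hyper grid enumerates the search space in tie-break order", {
  g <- hyper_grid()
  expect_equal(nrow(g), 12L)
  expect_equal(g$C[1:2], c(0.05, 0.05))
  expect_equal(g$solver[1:2], c("LS", "SMO"))
  expect_true(!is.unsorted(g$C))
})

test_that("inner LOOCV AUC is 1 for a label-revealing feature", {
  set.seed(12)
  y <- rep(c(1, -1), each = 8)
  X <- cbind(y, matrix(rnorm(16 * 20), 16, 20))
  for (solver in c("LS", "SMO")) {
    auc <- inner_cv_auc(X, y, list(solver = solver, C = 1, t_threshold = 2))
    expect_equal(auc, 1.0)
  }
})

test_that("constant features collapse to the anti-learning limit", {
  # within a fold the decision is the training-label mean, which always has
  # the sign opposite to the held-out label on balanced data: pooled AUC 0
  X <- matrix(0.3, 20, 5)
  y <- rep(c(1, -1), each = 10)
  auc <- inner_cv_auc(X, y, list(solver = "LS", C = 1, t_threshold = 2))
  expect_equal(auc, 0)
  # the rank-AUC tie rule itself scores truly constant decisions at 1/2
  expect_equal(rank_auc(rep(0.7, 20), y), 0.5)
})

test_that("pure-noise features give calibrated inner AUC", {
  y <- rep(c(1, -1), each = 10)
  cfg <- list(solver = "LS", C = 1, t_threshold = 2)
  aucs <- vapply(1:50, function(s) {
    set.seed(s)
    inner_cv_auc(matrix(rnorm(20 * 100), 20, 100), y, cfg)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("hyperparameter selection maximizes inner AUC with fixed tie order", {
  set.seed(13)
  y <- rep(c(1, -1), each = 8)
  X <- cbind(y + rnorm(16, sd = 0.1), matrix(rnorm(16 * 10), 16, 10))
  g1 <- hyper_grid(solvers = "LS", C = 0.5)
  one <- select_hyperparameters(X, y, g1)
  expect_equal(one$config$C, 0.5)

  # a strongly separable problem ties every config at AUC 1: the tie must
  # resolve to smallest C, then LS
  full <- select_hyperparameters(X, y, hyper_grid())
  expect_true(all(full$auc_table$auc <= full$auc))
  ties <- full$auc_table$auc == full$auc
  if (sum(ties) > 1) {
    expect_equal(full$config$C, min(full$auc_table$C[ties]))
    expect_equal(full$config$solver, "LS")
  }
})

test_that("nested LOOCV is perfect on strongly separable synthetic data", {
  cfg <- cohort_config(n_per_group = 8, n_voxels = 100, effect_fraction = 0.2,
                       effect_size = 6, noise_sd = 0.02, seed = 17)
  sim <- simulate_dataset(cfg)
  rs <- residualize_age(sim$stack, sim$cohort$age)
  fit <- run_nested_loocv(rs, sim$cohort$group)
  expect_equal(nrow(fit$outcomes), 16L)
  expect_setequal(fit$outcomes$subject_id, sim$cohort$subject_id)
  expect_equal(fit$outcomes$predicted, fit$outcomes$true)
  s <- summarize_outcomes(fit)
  expect_equal(s$point_auc, 100)

  # determinism: identical inputs give identical outcome tables
  fit2 <- run_nested_loocv(rs, sim$cohort$group)
  expect_identical(fit$outcomes, fit2$outcomes)

  expect_error(run_nested_loocv(rs$values[1:5, ], c(1, 1, 1, -1, -1)),
               "at least 3")
})

test_that("the held-out subject cannot influence its own fold's choices", {
  sim <- make_null_stack(n_per_group = 5, n_voxels = 60, seed = 23)
  y <- sim$cohort$group
  X <- sim$stack$values
  fit <- run_nested_loocv(X, y, hyper_grid(C = c(0.1, 1)))
  # perturb subject 1's voxel values wildly; its fold's screening,
  # hyperparameter choice and training set are untouched
  X2 <- X
  X2[1, ] <- rev(X2[1, ]) + 0.2
  fit2 <- run_nested_loocv(X2, y, hyper_grid(C = c(0.1, 1)))
  o1 <- fit$outcomes[1, ]
  o2 <- fit2$outcomes[1, ]
  expect_identical(o1[c("solver", "C", "t_threshold", "n_selected")],
                   o2[c("solver", "C", "t_threshold", "n_selected")])
  expect_identical(fit$selected_voxels[[1]], fit2$selected_voxels[[1]])
})

test_that("modal configuration reports maximum selection frequency", {
  mk <- function(solver, C, n) data.frame(
    subject_id = sprintf("%s%g_%d", solver, C, seq_len(n)), true = 1L,
    predicted = 1L, decision = 1, solver = solver, C = C, t_threshold = 2,
    stringsAsFactors = FALSE)
  outcomes <- rbind(mk("LS", 0.05, 120), mk("SMO", 0.1, 40))
  rec <- modal_configuration(outcomes)
  expect_equal(sum(rec$counts$count), 160)
  expect_equal(rec$modal$solver, "LS")
  expect_equal(rec$modal$C, 0.05)

  one <- modal_configuration(mk("SMO", 5, 1))
  expect_equal(one$modal$solver, "SMO")
  expect_equal(one$modal$C, 5)

  # ties resolve to smallest C, then LS
  tied <- rbind(mk("SMO", 0.1, 10), mk("LS", 0.5, 10), mk("LS", 0.1, 10))
  expect_equal(modal_configuration(tied)$modal$C, 0.1)
  expect_equal(modal_configuration(tied)$modal$solver, "LS")
})
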