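test_that("both solvers handle the symmetric two-point problem", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  for (C in c(0.05, 1, 10)) {
    ls <- train_ls(X, y, C)
    smo <- train_smo(X, y, C)
    expect_equal(ls$bias, 0, tolerance = 1e-10)
    expect_equal(smo$bias, 0, tolerance = 1e-10)
    expect_equal(predict_labels(ls, X), c(-1L, 1L))
    expect_equal(predict_labels(smo, X), c(-1L, 1L))
  }
  expect_error(train_smo(X, c(1, 1), 1), "both classes")
  expect_error(train_ls(X, c(1, 1), 1), "both classes")
})

test_that("LS-SVM duplication is equivalent to doubling the penalty", {
  set.seed(8)
  X <- matrix(rnorm(8), 4, 2)
  y <- c(1, 1, -1, -1)
  Xtest <- matrix(rnorm(10), 5, 2)
  m_dup <- train_ls(rbind(X, X), rep(y, 2), C = 1)
  m_2c <- train_ls(X, y, C = 2)
  expect_equal(decision_values(m_dup, Xtest), decision_values(m_2c, Xtest),
               tolerance = 1e-8)
})

test_that("separable problems are fit perfectly for C >= 1", {
  for (seed in 1:5) {
    prob <- make_separable_problem(n = 20, d = 5, margin = 2, seed = seed)
    for (C in c(1, 5, 10)) {
      ls <- train_ls(prob$X, prob$y, C)
      expect_equal(predict_labels(ls, prob$X), as.integer(prob$y))
    }
    # LS and SMO agree on training labels when the data are separable
    smo <- train_smo(prob$X, prob$y, C = 1)
    expect_equal(predict_labels(smo, prob$X),
                 predict_labels(train_ls(prob$X, prob$y, C = 1), prob$X))
  }
})

test_that("SMO satisfies dual feasibility and KKT at termination", {
  for (seed in 1:10) {
    prob <- make_random_problem(n = 25, d = 6, seed = seed)
    C <- c(0.05, 0.5, 5)[seed %% 3 + 1]
    m <- train_smo(prob$X, prob$y, C, tol = 1e-3)
    a <- m$diagnostics$alpha
    expect_true(all(a >= 0 & a <= C))
    expect_lt(abs(sum(a * prob$y)), 1e-3)
    expect_true(m$converged)
    expect_lte(m$diagnostics$kkt_violation, 1e-3)
  }
})

test_that("predictions are invariant under feature permutation", {
  prob <- make_random_problem(n = 20, d = 8, seed = 99)
  perm <- sample(8)
  m1 <- train_ls(prob$X, prob$y, C = 1)
  m2 <- train_ls(prob$X[, perm], prob$y, C = 1)
  expect_equal(decision_values(m1, prob$X),
               decision_values(m2, prob$X[, perm]), tolerance = 1e-8)
  # SMO reaches the optimum along a permutation-dependent path; at a tight
  # KKT tolerance the decisions coincide and the labels match exactly
  s1 <- train_smo(prob$X, prob$y, C = 1, tol = 1e-8)
  s2 <- train_smo(prob$X[, perm], prob$y, C = 1, tol = 1e-8)
  expect_equal(decision_values(s1, prob$X),
               decision_values(s2, prob$X[, perm]), tolerance = 1e-5)
  expect_identical(predict_labels(s1, prob$X),
                   predict_labels(s2, prob$X[, perm]))
})

test_that("decision values and the zero-decision tie rule", {
  m <- dmriclass:::new_linear_svm(weights = c(0, 0), bias = 0.5,
                                  solver = "LS", C = 1)
  expect_equal(predict_labels(m, matrix(rnorm(6), 3, 2)), rep(1L, 3))

  m2 <- dmriclass:::new_linear_svm(weights = c(1, 0), bias = 0,
                                   solver = "LS", C = 1)
  expect_equal(decision_values(m2, matrix(c(-2, 7), 1, 2)), -2)
  expect_equal(predict_labels(m2, matrix(c(-2, 7), 1, 2)), -1L)
  # exactly zero -> +1
  expect_equal(predict_labels(m2, matrix(c(0, 3), 1, 2)), 1L)
  expect_error(decision_values(m2, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("models serialize to JSON and back", {
  prob <- make_separable_problem(seed = 2)
  m <- train_smo(prob$X, prob$y, C = 0.5)
  path <- tempfile(fileext = ".json")
  svm_to_json(m, path)
  m2 <- svm_from_json(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$bias, m$bias)
  expect_equal(m2$solver, "SMO")
  expect_equal(decision_values(m2, prob$X), decision_values(m, prob$X))
})
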