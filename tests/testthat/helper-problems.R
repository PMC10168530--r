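# Shared fixtures for the SVM and cross-validation tests.

# Two-class Gaussian problem with class means +/- margin along the first axis:
# linearly separable with high probability for margin >= 2.
make_separable_problem <- function(n = 20, d = 5, margin = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(rnorm(n * d, sd = 0.3), n, d)
  X[, 1] <- X[, 1] + margin * y
  list(X = X, y = y)
}

make_random_problem <- function(n, d, seed) {
  set.seed(seed)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(X = matrix(rnorm(n * d), n, d), y = y)
}

# Soft-margin SVM dual objective at a feasible alpha.
svm_dual_objective <- function(alpha, K, y) {
  sum(alpha) - 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))
}

# Generic convex-QP solution of the SVM dual via kernlab's interior-point
# solver (independent of the in-package SMO). A tiny ridge keeps the
# rank-deficient linear-kernel Hessian numerically positive definite.
qp_oracle_alpha <- function(K, y, C) {
  n <- length(y)
  H <- (y %o% y) * K + diag(1e-8, n)
  qp <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0, r = 0,
                      l = rep(0, n), u = rep(C, n), sigf = 9, maxiter = 300)
  kernlab::primal(qp)
}

# Small null metric stack for screening / CV tests.
make_null_stack <- function(n_per_group = 10, n_voxels = 100, seed = 1,
                            age_slope = 0) {
  cfg <- cohort_config(n_per_group = n_per_group, n_voxels = n_voxels,
                       effect_fraction = 0, age_slope = age_slope, seed = seed)
  simulate_dataset(cfg)
}
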