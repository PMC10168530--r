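new_linear_svm <- function(weights, bias, solver, C, converged = TRUE,
                           iterations = NA_integer_, diagnostics = list(),
                           selected_voxels = NULL) {
  if (any(!is.finite(weights)) || !is.finite(bias))
    stop("non-finite model coefficients", call. = FALSE)
  structure(list(weights = as.numeric(weights), bias = as.numeric(bias),
                 solver = solver, C = C, converged = converged,
                 iterations = iterations, diagnostics = diagnostics,
                 selected_voxels = selected_voxels),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> solver=%s C=%g, %d features, bias=%.4g%s\n",
              x$solver, x$C, length(x$weights), x$bias,
              if (!isTRUE(x$converged)) " [not converged]" else ""))
  invisible(x)
}

check_problem <- function(X, y, C) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1 || C <= 0)
    stop("C must be a single positive number", call. = FALSE)
  X
}

# Minimum-norm solve via SVD pseudoinverse (singular LS-SVM systems).
pinv_solve <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' Train a least-squares SVM (linear kernel)
#'
#' Solves the LS-SVM dual — squared-error loss with equality constraints —
#' as the single bordered linear system
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + I/C \end{pmatrix}
#'   \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'   \begin{pmatrix} 0 \\ y \end{pmatrix}, \quad K = X X^T,}
#' with the primal weights recovered as `w = X' alpha`. A numerically
#' singular system falls back to the minimum-norm solution with a warning.
#'
#' Note the duplication identity of this loss: duplicating every training
#' point at penalty `C` gives the same decision function as the original
#' points at penalty `2C`.
#'
#' @param X Feature matrix, subjects in rows.
#' @param y +1/-1 labels.
#' @param C Soft-margin penalty (> 0).
#' @param gram Optional precomputed `tcrossprod(X)` (results are identical
#'   with or without it).
#' @return A `linear_svm` model (`solver = "LS"`), with the linear-system
#'   residual norm under `diagnostics`.
#' @export
train_ls <- function(X, y, C, gram = NULL) {
  X <- check_problem(X, y, C)
  n <- nrow(X)
  K <- if (is.null(gram)) tcrossprod(X) else gram
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warning("singular LS-SVM system: using minimum-norm solution")
    pinv_solve(A, rhs)
  })
  bias <- sol[1]
  alpha <- sol[-1]
  w <- drop(crossprod(X, alpha))
  new_linear_svm(w, bias, "LS", C,
                 diagnostics = list(residual_norm = sqrt(sum((A %*% sol - rhs)^2)),
                                    alpha = alpha))
}

#' Train a soft-margin SVM by sequential minimal optimization
#'
#' Solves the standard hinge-loss dual (`0 <= alpha_i <= C`, `sum alpha_i
#' y_i = 0`) by pairwise coordinate ascent on the maximal KKT-violating
#' pair, terminating when the maximal violation drops to `tol` or after
#' `max_iter` pair updates (the model is then flagged, not rejected). The
#' weights are `w = sum_i alpha_i y_i x_i`; the bias is averaged over free
#' support vectors (`0 < alpha_i < C`).
#'
#' @inheritParams train_ls
#' @param tol KKT violation tolerance; default 1e-3.
#' @param max_iter Maximum pair updates; default `2000 * n`, ample for the
#'   problem sizes screened features produce.
#' @return A `linear_svm` model (`solver = "SMO"`) with `converged`,
#'   `iterations` and the final KKT violation in `diagnostics`.
#' @export
train_smo <- function(X, y, C, tol = 1e-3, max_iter = NULL, gram = NULL) {
  X <- check_problem(X, y, C)
  n <- nrow(X)
  if (is.null(max_iter)) max_iter <- 2000L * n
  K <- if (is.null(gram)) tcrossprod(X) else gram
  fit <- smo_solve(K, as.numeric(y), C, tol, as.integer(max_iter))
  w <- drop(crossprod(X, fit$alpha * y))
  new_linear_svm(w, fit$b, "SMO", C,
                 converged = fit$converged,
                 iterations = fit$iterations,
                 diagnostics = list(kkt_violation = fit$kkt_violation,
                                    alpha = fit$alpha))
}

#' Decision values and hard predictions of a linear model
#'
#' `decision_values` returns `f(x) = w . x + b` per row;
#' `predict_labels` maps it to +1/-1 with the fixed tie rule that a decision
#' value of exactly 0 predicts +1 (keeps leave-one-out runs deterministic).
#'
#' @param model A `linear_svm`.
#' @param X Matrix of rows to score (feature dimension must match).
#' @return Numeric decision values / integer +1/-1 labels.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "linear_svm"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights))
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 length(model$weights), ncol(X)), call. = FALSE)
  drop(X %*% model$weights) + model$bias
}

#' @rdname decision_values
#' @export
predict_labels <- function(model, X) {
  d <- decision_values(model, X)
  ifelse(d >= 0, 1L, -1L)
}

#' Serialize / restore a linear SVM model as JSON
#'
#' @param model A `linear_svm`.
#' @param path File path.
#' @return `svm_from_json` returns the restored `linear_svm`.
#' @export
svm_to_json <- function(model, path) {
  stopifnot(inherits(model, "linear_svm"))
  out <- model[c("weights", "bias", "solver", "C", "converged", "iterations",
                 "selected_voxels")]
  out$diagnostics <- model$diagnostics[setdiff(names(model$diagnostics), "alpha")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname svm_to_json
#' @export
svm_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_linear_svm(x$weights, x$bias, x$solver, x$C,
                 converged = x$converged %||% TRUE,
                 iterations = x$iterations %||% NA_integer_,
                 diagnostics = as.list(x$diagnostics),
                 selected_voxels = x$selected_voxels)
}
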