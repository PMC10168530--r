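#' Hyperparameter grid for the nested cross-validation search
#'
#' The searched configurations: solver (LS or SMO) x soft-margin penalty C x
#' screening t-threshold. Rows are kept in the fixed tie-breaking order —
#' smallest C first, LS before SMO, smallest t-threshold first — so that
#' "first maximal AUC" implements the documented tie rule.
#'
#' @param solvers Subset of `c("LS", "SMO")`.
#' @param C Soft-margin penalties; default the six searched values.
#' @param t_threshold Screening thresholds; default the single value 2.0.
#' @return A `data.frame` of class `hyper_grid` with columns `solver`, `C`,
#'   `t_threshold`.
#' @export
hyper_grid <- function(solvers = c("LS", "SMO"),
                       C = c(0.05, 0.1, 0.5, 1.0, 5.0, 10.0),
                       t_threshold = 2.0) {
  solvers <- match.arg(solvers, several.ok = TRUE)
  g <- expand.grid(solver = solvers, C = C, t_threshold = t_threshold,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$C, match(g$solver, c("LS", "SMO")), g$t_threshold), ,
         drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("hyper_grid", "data.frame")
  g
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation over continuous decision values; tied values
#' contribute 1/2 through midranks.
#'
#' @param decisions Numeric decision values.
#' @param labels +1/-1 labels.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
rank_auc <- function(decisions, labels) {
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(decisions)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

train_config <- function(X, y, solver, C, gram = NULL, tol = 1e-3) {
  if (solver == "LS") train_ls(X, y, C, gram = gram)
  else train_smo(X, y, C, tol = tol, gram = gram)
}

# Inner LOOCV held-out decision values for every grid row.
# Screening is recomputed on each inner-training set (unless t_override
# supplies precomputed "leaky" t values); the Gram matrix of the screened
# training block is computed once per inner fold and shared across configs.
inner_cv_decisions <- function(X, y, grid, t_override = NULL, tol = 1e-3) {
  n <- nrow(X)
  dec <- matrix(NA_real_, n, nrow(grid))
  skipped <- logical(n)
  thresholds <- unique(grid$t_threshold)
  cfg_by_thr <- lapply(thresholds, function(th) which(grid$t_threshold == th))
  for (i in seq_len(n)) {
    tr <- seq_len(n)[-i]
    ytr <- y[tr]
    if (sum(ytr == 1) < 2 || sum(ytr == -1) < 2) {
      skipped[i] <- TRUE
      next
    }
    Xtr <- X[tr, , drop = FALSE]
    tv <- if (is.null(t_override)) voxelwise_t(Xtr, ytr)$t else t_override
    for (h in seq_along(thresholds)) {
      sel <- select_voxels(tv, thresholds[h])$selected
      Xs <- Xtr[, sel, drop = FALSE]
      K <- tcrossprod(Xs)
      xi <- X[i, sel, drop = FALSE]
      for (k in cfg_by_thr[[h]]) {
        m <- train_config(Xs, ytr, grid$solver[k], grid$C[k], gram = K, tol = tol)
        dec[i, k] <- decision_values(m, xi)
      }
    }
  }
  list(decisions = dec, skipped = skipped)
}

#' Inner leave-one-out AUC of one hyperparameter configuration
#'
#' Runs LOOCV over the supplied (outer-training) rows: per inner fold the
#' voxels are re-screened on the inner-training rows at the configuration's
#' t-threshold, the model is trained with the configuration's solver and C,
#' and the held-out decision value recorded. The AUC is the rank-based ROC
#' area of the pooled held-out decision values against the labels.
#' Degenerate inner folds (a class vanishing from the inner-training rows)
#' are skipped.
#'
#' @param X Subjects-by-voxels matrix (outer-training rows).
#' @param y +1/-1 labels.
#' @param config A list / one-row data.frame with `solver`, `C`,
#'   `t_threshold`.
#' @param tol SMO tolerance.
#' @return Inner AUC scalar.
#' @export
inner_cv_auc <- function(X, y, config, tol = 1e-3) {
  grid <- data.frame(solver = config$solver, C = config$C,
                     t_threshold = config$t_threshold,
                     stringsAsFactors = FALSE)
  res <- inner_cv_decisions(as.matrix(X), y, grid, tol = tol)
  ok <- !res$skipped
  rank_auc(res$decisions[ok, 1], y[ok])
}

#' Select the maximum-inner-AUC hyperparameter configuration
#'
#' Evaluates every grid row by [inner_cv_auc()] (shared inner folds) and
#' returns the argmax. Ties resolve to the earliest grid row, i.e. smallest
#' C, then LS before SMO, then smallest t-threshold.
#'
#' @inheritParams inner_cv_auc
#' @param grid A [hyper_grid()].
#' @param t_override Internal: precomputed t values for the deliberate
#'   leaky-screening mode.
#' @return List: `config` (one-row data.frame), `auc`, `auc_table` (grid
#'   plus an `auc` column).
#' @export
select_hyperparameters <- function(X, y, grid, tol = 1e-3, t_override = NULL) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  X <- as.matrix(X)
  res <- inner_cv_decisions(X, y, grid, t_override = t_override, tol = tol)
  ok <- !res$skipped
  auc <- apply(res$decisions[ok, , drop = FALSE], 2, rank_auc, labels = y[ok])
  best <- which.max(auc)
  tab <- cbind(as.data.frame(grid), auc = auc)
  list(config = as.data.frame(grid)[best, , drop = FALSE],
       auc = auc[best], auc_table = tab)
}

#' Nested leave-one-out cross-validation of the voxelwise SVM pipeline
#'
#' For each subject s: hold s out; on the remaining subjects run an inner
#' LOOCV over the full hyperparameter grid (per inner fold: re-screen voxels
#' by two-sample t at the candidate threshold, train the candidate solver/C,
#' record the held-out decision value) and pick the maximum-inner-AUC
#' configuration; re-screen on all outer-training rows at the chosen
#' threshold, train the chosen model, and predict s. The held-out subject
#' never influences screening, training or hyperparameter selection of its
#' own fold.
#'
#' Two deliberate departures from that hygiene are available for
#' sensitivity/demonstration work: `leaky_screening = TRUE` computes the
#' screening t values once from ALL subjects (the classic selection-leakage
#' mistake), and `fold_safe_residualize = TRUE` re-fits the voxelwise age
#' regression on each fold's training rows only (the default replicates the
#' conventional whole-sample age regression performed before
#' cross-validation, so pass an already-residualized stack).
#'
#' @param stack A [metric_stack()] (typically residualized) or a plain
#'   subjects-by-voxels matrix.
#' @param labels +1/-1 group labels (>= 3 per class).
#' @param grid A [hyper_grid()].
#' @param ages Subject ages; required when `fold_safe_residualize = TRUE`.
#' @param fold_safe_residualize Re-fit the age regression per outer fold on
#'   training rows only.
#' @param leaky_screening Use whole-sample screening (demonstration mode).
#' @param tol SMO tolerance.
#' @param verbose Print a progress line per fold.
#' @return Object of class `nested_loocv`: `outcomes` (one row per subject:
#'   `subject_id`, `true`, `predicted`, `decision`, `solver`, `C`,
#'   `t_threshold`, `inner_auc`, `n_selected`, `screening_fallback`),
#'   `selected_voxels` (per-fold integer index lists), `grid`, `settings`.
#' @export
run_nested_loocv <- function(stack, labels, grid = hyper_grid(),
                             ages = NULL, fold_safe_residualize = FALSE,
                             leaky_screening = FALSE, tol = 1e-3,
                             verbose = FALSE) {
  if (inherits(stack, "metric_stack")) {
    X <- stack$values
    ids <- stack$subject_ids
  } else {
    X <- as.matrix(stack)
    ids <- rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  }
  n <- nrow(X)
  if (length(labels) != n) stop("labels length must match subjects", call. = FALSE)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (sum(labels == 1) < 3 || sum(labels == -1) < 3)
    stop("nested LOOCV needs at least 3 subjects per class", call. = FALSE)
  if (fold_safe_residualize && is.null(ages))
    stop("fold_safe_residualize = TRUE requires 'ages'", call. = FALSE)

  t_global <- if (leaky_screening) voxelwise_t(X, labels)$t else NULL

  outcomes <- vector("list", n)
  selected_voxels <- vector("list", n)
  for (s in seq_len(n)) {
    tr <- seq_len(n)[-s]
    Xf <- if (fold_safe_residualize) {
      resid_matrix(X, ages, fit_rows = tr)
    } else X
    hp <- select_hyperparameters(Xf[tr, , drop = FALSE], labels[tr], grid,
                                 tol = tol, t_override = t_global)
    cfg <- hp$config
    tv <- if (leaky_screening) t_global
          else voxelwise_t(Xf[tr, , drop = FALSE], labels[tr])$t
    sel <- select_voxels(tv, cfg$t_threshold)
    Xs <- Xf[tr, sel$selected, drop = FALSE]
    model <- train_config(Xs, labels[tr], cfg$solver, cfg$C, tol = tol)
    d <- decision_values(model, Xf[s, sel$selected, drop = FALSE])
    outcomes[[s]] <- data.frame(
      subject_id = ids[s], true = labels[s],
      predicted = if (d >= 0) 1L else -1L, decision = d,
      solver = cfg$solver, C = cfg$C, t_threshold = cfg$t_threshold,
      inner_auc = hp$auc, n_selected = length(sel$selected),
      screening_fallback = sel$fallback_used,
      stringsAsFactors = FALSE)
    selected_voxels[[s]] <- sel$selected
    if (verbose)
      message(sprintf("fold %d/%d: %s C=%g |sel|=%d -> pred %+d (true %+d)",
                      s, n, cfg$solver, cfg$C, length(sel$selected),
                      outcomes[[s]]$predicted, labels[s]))
  }
  structure(list(
    outcomes = do.call(rbind, outcomes),
    selected_voxels = selected_voxels,
    grid = grid,
    settings = list(leaky_screening = leaky_screening,
                    fold_safe_residualize = fold_safe_residualize,
                    tol = tol)
  ), class = "nested_loocv")
}

# matrix-level age residualization (shared with residualize_age)
resid_matrix <- function(X, ages, fit_rows) {
  a <- ages[fit_rows]
  a_mean <- mean(a)
  a_c <- a - a_mean
  ss <- sum(a_c^2)
  col_mean <- colMeans(X[fit_rows, , drop = FALSE])
  slope <- if (ss == 0) numeric(ncol(X))
           else as.numeric(crossprod(a_c, X[fit_rows, , drop = FALSE])) / ss
  X - matrix(col_mean, nrow(X), ncol(X), byrow = TRUE) -
    outer(ages - a_mean, slope)
}

#' Modal hyperparameter configuration over the outer folds
#'
#' Tallies how often each configuration was selected across outer folds and
#' reports the most frequent one (maximum frequency of selection); ties
#' resolve by smallest C, then LS before SMO, then smallest t-threshold.
#'
#' @param x A [run_nested_loocv()] result or its `outcomes` data.frame.
#' @return Object of class `selection_record`: `counts` (configurations with
#'   selection counts, tie-break order) and `modal` (one-row data.frame).
#' @export
modal_configuration <- function(x) {
  outcomes <- if (inherits(x, "nested_loocv")) x$outcomes else x
  if (NROW(outcomes) == 0) stop("no fold outcomes", call. = FALSE)
  counts <- aggregate(list(count = rep(1L, nrow(outcomes))),
                      by = outcomes[c("solver", "C", "t_threshold")], FUN = sum)
  counts <- counts[order(counts$C, match(counts$solver, c("LS", "SMO")),
                         counts$t_threshold), , drop = FALSE]
  rownames(counts) <- NULL
  modal <- counts[which.max(counts$count), c("solver", "C", "t_threshold"),
                  drop = FALSE]
  structure(list(counts = counts, modal = modal, n_folds = nrow(outcomes)),
            class = "selection_record")
}

#' @export
print.selection_record <- function(x, ...) {
  cat(sprintf("<selection_record> %d folds; modal: %s C=%g t=%g\n",
              x$n_folds, x$modal$solver, x$modal$C, x$modal$t_threshold))
  print(x$counts)
  invisible(x)
}
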