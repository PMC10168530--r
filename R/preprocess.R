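#' White-matter mask from a mean-FA threshold
#'
#' Averages the FA stack over subjects and keeps voxels whose mean FA is
#' greater than or equal to the threshold (the inclusive semantics of the
#' standard image-thresholding utilities).
#'
#' @param fa_stack A pre-residualization FA [metric_stack()].
#' @param threshold Mean-FA cutoff; default 0.20.
#' @return Object of class `wm_mask`: `keep` (logical per stack column),
#'   `voxel_index_map`, `grid_shape`, `threshold`.
#' @export
build_wm_mask <- function(fa_stack, threshold = 0.20) {
  stopifnot(inherits(fa_stack, "metric_stack"))
  if (fa_stack$metric_name != "FA")
    stop("WM mask is defined from an FA stack", call. = FALSE)
  if (fa_stack$residualized)
    stop("WM mask must be built from the raw (pre-residualization) FA stack",
         call. = FALSE)
  keep <- colMeans(fa_stack$values) >= threshold
  if (!any(keep))
    stop(sprintf(
      "empty WM mask at threshold %.3g: review the threshold against the mean FA image",
      threshold), call. = FALSE)
  structure(list(keep = keep,
                 voxel_index_map = fa_stack$voxel_index_map,
                 grid_shape = fa_stack$grid_shape,
                 threshold = threshold),
            class = "wm_mask")
}

#' Restrict a metric stack to a mask
#'
#' @param stack A [metric_stack()] on the same grid as the mask.
#' @param mask A [build_wm_mask()] result (or a logical vector over the
#'   stack's columns).
#' @return The masked [metric_stack()].
#' @export
apply_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "metric_stack"))
  if (inherits(mask, "wm_mask")) {
    if (!identical(mask$grid_shape, stack$grid_shape))
      stop("mask and stack grids differ", call. = FALSE)
    keep <- mask$keep
  } else {
    keep <- as.logical(mask)
  }
  if (length(keep) != ncol(stack$values))
    stop("mask length must match the number of stack voxels", call. = FALSE)
  metric_stack(stack$values[, keep, drop = FALSE],
               subject_ids = stack$subject_ids,
               metric_name = stack$metric_name,
               voxel_index_map = stack$voxel_index_map[keep],
               grid_shape = stack$grid_shape,
               residualized = stack$residualized)
}

#' Residualize age out of every voxel
#'
#' Per voxel, fits `value ~ intercept + age` by simple linear regression on
#' the `fit_rows` subset and subtracts the fitted prediction from ALL rows.
#' With `fit_rows` equal to all subjects this reproduces the whole-sample
#' age regression applied before classification; passing only the training
#' rows of a cross-validation fold gives the leakage-free variant.
#'
#' If the fit rows have zero age variance the slope is set to 0 (residual =
#' value minus the fit-row mean) with a warning.
#'
#' @param stack A [metric_stack()].
#' @param ages Numeric vector of ages, one per stack row.
#' @param fit_rows Integer indices of rows used to fit the regression
#'   (default: all rows). At least 2.
#' @return A residualized [metric_stack()] (`residualized = TRUE`); the mean
#'   residual over `fit_rows` is 0 at every voxel (to 1e-10).
#' @export
residualize_age <- function(stack, ages, fit_rows = seq_len(nrow(stack$values))) {
  stopifnot(inherits(stack, "metric_stack"))
  X <- stack$values
  if (length(ages) != nrow(X))
    stop("ages length must match the number of subjects", call. = FALSE)
  fit_rows <- as.integer(fit_rows)
  if (length(fit_rows) < 2 || any(fit_rows < 1 | fit_rows > nrow(X)))
    stop("fit_rows must index at least 2 valid subjects", call. = FALSE)
  a <- ages[fit_rows]
  a_mean <- mean(a)
  a_c <- a - a_mean
  ss <- sum(a_c^2)
  col_mean <- colMeans(X[fit_rows, , drop = FALSE])
  if (ss == 0) {
    warning("zero age variance in fit_rows: slope set to 0, residual = value - mean")
    slope <- numeric(ncol(X))
  } else {
    slope <- as.numeric(crossprod(a_c, X[fit_rows, , drop = FALSE])) / ss
  }
  # prediction for every row: col_mean + slope * (age - mean(fit ages))
  pred <- matrix(col_mean, nrow = nrow(X), ncol = ncol(X), byrow = TRUE) +
    outer(ages - a_mean, slope)
  metric_stack(X - pred,
               subject_ids = stack$subject_ids,
               metric_name = stack$metric_name,
               voxel_index_map = stack$voxel_index_map,
               grid_shape = stack$grid_shape,
               residualized = TRUE)
}
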