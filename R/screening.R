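#' Mass-univariate two-sample t statistics per voxel
#'
#' Pooled-variance (Student) two-sample t at every voxel, signed as
#' `(mean TBI+ - mean TBI-) / SE`, df = n1 + n2 - 2. Voxels with zero pooled
#' variance get `t = +/-Inf` (sign of the mean difference; 0 when the means
#' also agree) and are flagged.
#'
#' @param values Subjects-by-voxels matrix (typically residualized), or a
#'   [metric_stack()].
#' @param labels Numeric +1/-1 group labels, one per row; both groups need
#'   at least 2 subjects.
#' @return List of class `screening_t`: `t` (per voxel), `df`,
#'   `zero_variance` (logical per voxel).
#' @export
voxelwise_t <- function(values, labels) {
  if (inherits(values, "metric_stack")) values <- values$values
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be +1/-1", call. = FALSE)
  g1 <- labels == 1
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 subjects for the t statistic", call. = FALSE)
  X1 <- values[g1, , drop = FALSE]
  X2 <- values[!g1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2, m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  tt <- diff / se
  zv <- sp2 == 0
  if (any(zv)) tt[zv] <- sign(diff[zv]) * Inf  # sign 0 -> 0 (NaN avoided)
  tt[zv & diff == 0] <- 0
  structure(list(t = as.numeric(tt), df = df, zero_variance = zv),
            class = "screening_t")
}

#' Select voxels by absolute t threshold
#'
#' Keeps voxels with `|t| >= threshold`, in ascending index order. If the
#' selection is empty and `fallback` is TRUE, the single largest-|t| voxel
#' is selected and the result flagged, so every cross-validation fold can
#' still emit a prediction.
#'
#' @param t_values Numeric t vector, or a [voxelwise_t()] result.
#' @param threshold Absolute-t cutoff; default 2.0.
#' @param fallback Apply the top-1 fallback on empty selections?
#' @return List of class `voxel_selection`: `selected` (ascending 1-based
#'   indices), `threshold`, `fallback_used`.
#' @export
select_voxels <- function(t_values, threshold = 2.0, fallback = TRUE) {
  if (inherits(t_values, "screening_t")) t_values <- t_values$t
  at <- abs(t_values)
  sel <- which(at >= threshold)
  fb <- FALSE
  if (length(sel) == 0) {
    if (!fallback)
      stop("no voxel exceeds the t threshold", call. = FALSE)
    sel <- which.max(at)
    fb <- TRUE
  }
  structure(list(selected = sort(sel), threshold = threshold, fallback_used = fb),
            class = "voxel_selection")
}
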