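#' Voxelwise metric stack container
#'
#' A subjects-by-voxels matrix of one diffusion scalar metric plus the grid
#' metadata needed to round-trip volumetric files. Voxel linear indices are
#' x-fastest over the 3D grid (1-based inside R; sidecar files use 0-based
#' indices).
#'
#' @param values Numeric matrix, subjects in rows, voxels in columns.
#' @param subject_ids Character vector, one id per row.
#' @param metric_name One of `"FA"`, `"ODI"`, `"Viso"`.
#' @param voxel_index_map Integer vector of 1-based linear grid indices for
#'   the columns (defaults to `1:ncol(values)`).
#' @param grid_shape Integer length-3 grid dimensions; defaults to a flat
#'   `c(n_voxels, 1, 1)` grid.
#' @param residualized Logical flag: residualized stacks may hold values
#'   outside `[0, 1]`.
#' @return An object of class `metric_stack`.
#' @export
metric_stack <- function(values, subject_ids,
                         metric_name = c("FA", "ODI", "Viso"),
                         voxel_index_map = NULL,
                         grid_shape = NULL,
                         residualized = FALSE) {
  metric_name <- match.arg(metric_name)
  values <- as.matrix(values)
  if (length(subject_ids) != nrow(values))
    stop("length(subject_ids) must equal nrow(values)", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("subject_ids must be unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("metric values must be finite", call. = FALSE)
  if (!residualized && (min(values) < 0 || max(values) > 1))
    stop(sprintf("%s values must lie in [0, 1] before residualization", metric_name),
         call. = FALSE)
  if (is.null(grid_shape)) grid_shape <- c(ncol(values), 1L, 1L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3)
    stop("grid_shape must have 3 dimensions", call. = FALSE)
  if (is.null(voxel_index_map)) voxel_index_map <- seq_len(ncol(values))
  voxel_index_map <- as.integer(voxel_index_map)
  if (length(voxel_index_map) != ncol(values))
    stop("voxel_index_map length must equal ncol(values)", call. = FALSE)
  if (any(voxel_index_map < 1L | voxel_index_map > prod(grid_shape)))
    stop("voxel_index_map indices outside the grid", call. = FALSE)
  structure(list(
    values = values,
    subject_ids = as.character(subject_ids),
    metric_name = metric_name,
    voxel_index_map = voxel_index_map,
    grid_shape = grid_shape,
    residualized = isTRUE(residualized)
  ), class = "metric_stack")
}

#' @export
print.metric_stack <- function(x, ...) {
  cat(sprintf("<metric_stack> %s: %d subjects x %d voxels (grid %s)%s\n",
              x$metric_name, nrow(x$values), ncol(x$values),
              paste(x$grid_shape, collapse = "x"),
              if (x$residualized) ", residualized" else ""))
  invisible(x)
}

#' @export
dim.metric_stack <- function(x) dim(x$values)
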