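stack_to_array <- function(stack) {
  flat <- matrix(0, prod(stack$grid_shape), nrow(stack$values))
  flat[stack$voxel_index_map, ] <- t(stack$values)
  array(flat, dim = c(stack$grid_shape, nrow(stack$values)))
}

#' Write / read a metric stack as a 4D NIfTI volume
#'
#' The stack is written as one 4D NIfTI-1 file (x, y, z, subject) plus a
#' `subjects.tsv` sidecar whose row order records the volume order. Voxel
#' linearization is x-fastest; sidecar indices are 0-based.
#'
#' @param stack A [metric_stack()].
#' @param path Output NIfTI path (`.nii` / `.nii.gz`).
#' @param subjects Optional subject table to write alongside; defaults to a
#'   minimal table of the stack's subject ids.
#' @return `write_metric_stack` invisibly returns `path`.
#' @export
write_metric_stack <- function(stack, path, subjects = NULL) {
  stopifnot(inherits(stack, "metric_stack"))
  RNifti::writeNifti(stack_to_array(stack), path)
  if (is.null(subjects))
    subjects <- data.frame(subject_id = stack$subject_ids,
                           stringsAsFactors = FALSE)
  write_subjects_tsv(subjects, file.path(dirname(path), "subjects.tsv"))
  invisible(path)
}

#' @rdname write_metric_stack
#' @param subjects_table Subject table (data.frame, or path to a TSV with a
#'   `subject_id` column) giving the desired row order; rows are aligned to
#'   it by id.
#' @param volume_ids Subject ids in volume order; defaults to the
#'   `subjects.tsv` sidecar next to `path`, else to the table order.
#' @param metric_name Metric stored in the file.
#' @param mask Optional [build_wm_mask()] result or logical vector selecting
#'   grid voxels; default keeps every grid voxel.
#' @export
read_metric_stack <- function(path, subjects_table, volume_ids = NULL,
                              metric_name = c("FA", "ODI", "Viso"),
                              mask = NULL) {
  metric_name <- match.arg(metric_name)
  if (is.character(subjects_table)) subjects_table <- read_subjects_tsv(subjects_table)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) arr <- array(arr, dim = c(dim(arr), 1))
  if (length(dim(arr)) != 4)
    stop(sprintf("'%s' is not a 3D/4D volume", path), call. = FALSE)
  grid <- dim(arr)[1:3]
  ns <- dim(arr)[4]
  if (is.null(volume_ids)) {
    sidecar <- file.path(dirname(path), "subjects.tsv")
    volume_ids <- if (file.exists(sidecar)) read_subjects_tsv(sidecar)$subject_id
                  else subjects_table$subject_id
  }
  if (length(volume_ids) != ns)
    stop(sprintf("'%s' has %d volumes but %d subject ids were given",
                 path, ns, length(volume_ids)), call. = FALSE)
  missing_ids <- setdiff(subjects_table$subject_id, volume_ids)
  if (length(missing_ids))
    stop(sprintf("subject '%s' not found among the volumes of '%s'",
                 missing_ids[1], path), call. = FALSE)
  flat <- matrix(arr, prod(grid), ns)  # column-major = x-fastest linearization
  bad <- which(!is.finite(flat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite voxel at linear index %d (0-based %d) in '%s'",
                 bad[1, 1], bad[1, 1] - 1L, path), call. = FALSE)
  keep <- if (is.null(mask)) rep(TRUE, prod(grid))
          else if (inherits(mask, "wm_mask")) mask$keep else as.logical(mask)
  values <- t(flat[keep, , drop = FALSE])
  rows <- match(subjects_table$subject_id, volume_ids)
  metric_stack(values[rows, , drop = FALSE],
               subject_ids = subjects_table$subject_id,
               metric_name = metric_name,
               voxel_index_map = which(keep),
               grid_shape = grid)
}

#' Read / write the subject covariate table (TSV)
#'
#' @param subjects Data.frame with at least `subject_id`.
#' @param path TSV path.
#' @return `read_subjects_tsv` returns the data.frame.
#' @export
write_subjects_tsv <- function(subjects, path) {
  stopifnot("subject_id" %in% names(subjects))
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects_tsv
#' @export
read_subjects_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop(sprintf("'%s' lacks the required subject_id column", path), call. = FALSE)
  df
}

#' Write a WM mask as a byte-valued NIfTI volume
#'
#' @param mask A [build_wm_mask()] result.
#' @param path Output path.
#' @export
write_wm_mask <- function(mask, path) {
  stopifnot(inherits(mask, "wm_mask"))
  vol <- numeric(prod(mask$grid_shape))
  vol[mask$voxel_index_map[mask$keep]] <- 1
  RNifti::writeNifti(array(vol, dim = mask$grid_shape), path,
                     datatype = "uint8")
  invisible(path)
}

#' Write the simulation ground truth as JSON (0-based indices)
#'
#' @param truth `ground_truth_effect` from [generate_metric_stack()].
#' @param path Output path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    affected_voxel_indices = as.integer(truth$affected) - 1L,
    shift = truth$shift,
    indexing = "0-based, x-fastest"
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read the per-fold outcome log (TSV)
#'
#' One row per outer fold: held-out subject, truth, prediction, decision
#' value, selected configuration, number of screened voxels, fallback flag.
#'
#' @param x A [run_nested_loocv()] result or its `outcomes` data.frame.
#' @param path TSV path.
#' @return `read_folds_tsv` returns the outcomes data.frame.
#' @export
write_folds_tsv <- function(x, path) {
  outcomes <- if (inherits(x, "nested_loocv")) x$outcomes else x
  write.table(outcomes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds_tsv
#' @export
read_folds_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write the classification summary / selection record as JSON
#'
#' @param x A `classification_summary` or `selection_record`.
#' @param path Output path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Echo a run configuration (with package version and seed) as JSON
#'
#' @param config Named list of run settings; must include `seed`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("dmriclass"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
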