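#' Classification summary from confusion counts
#'
#' Builds the report the pipeline prints per feature set: confusion counts
#' within each group, sensitivity = TP/(TP+FN) (correct rate within the
#' positive, TBI+, group), specificity = TN/(TN+FP) (correct rate within
#' the negative group), and the single-operating-point "point AUC" —
#' the area under the ROC formed by the hard leave-one-out decisions,
#' which equals (sensitivity + specificity)/2. If decision values are
#' supplied, the continuous rank AUC is reported as an auxiliary column.
#' Rates are stored as percentages (two printed decimals, half-up).
#'
#' @param tp,fn True positives / false negatives (within the +1 group).
#' @param tn,fp True negatives / false positives (within the -1 group).
#' @param decisions,labels Optional decision values and +1/-1 labels for the
#'   auxiliary rank AUC.
#' @return Object of class `classification_summary`.
#' @export
classification_summary <- function(tp, fn, tn, fp,
                                   decisions = NULL, labels = NULL) {
  tp <- unname(as.numeric(tp)); fn <- unname(as.numeric(fn))
  tn <- unname(as.numeric(tn)); fp <- unname(as.numeric(fp))
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("both classes must be present", call. = FALSE)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  rauc <- if (!is.null(decisions)) 100 * rank_auc(decisions, labels) else NA_real_
  structure(list(
    tp = as.integer(tp), fn = as.integer(fn),
    tn = as.integer(tn), fp = as.integer(fp),
    n_positive = as.integer(tp + fn), n_negative = as.integer(tn + fp),
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    point_auc = 100 * point_auc(sens, spec),
    rank_auc = rauc
  ), class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf(
    "<classification_summary> TP=%d FN=%d TN=%d FP=%d\n  AUC %s%%  sensitivity %s%%  specificity %s%%%s\n",
    x$tp, x$fn, x$tn, x$fp,
    format(round_half_up(x$point_auc, 2), nsmall = 2),
    format(round_half_up(x$sensitivity, 2), nsmall = 2),
    format(round_half_up(x$specificity, 2), nsmall = 2),
    if (is.na(x$rank_auc)) ""
    else sprintf("  (rank AUC %s%%)", format(round_half_up(x$rank_auc, 2), nsmall = 2))))
  invisible(x)
}

#' Single-operating-point AUC
#'
#' Area under the two-segment ROC through the single operating point
#' `(1 - specificity, sensitivity)`: `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
point_auc <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) || any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  (sensitivity + specificity) / 2
}

#' Summarize fold outcomes into classification rates
#'
#' @param x A [run_nested_loocv()] result or its `outcomes` data.frame
#'   (columns `true`, `predicted`, optionally `decision`).
#' @return A [classification_summary()].
#' @export
summarize_outcomes <- function(x) {
  outcomes <- if (inherits(x, "nested_loocv")) x$outcomes else x
  if (NROW(outcomes) == 0) stop("no fold outcomes", call. = FALSE)
  if (!all(c(1, -1) %in% outcomes$true))
    stop("both classes must be present in the outcomes", call. = FALSE)
  classification_summary(
    tp = sum(outcomes$true == 1 & outcomes$predicted == 1),
    fn = sum(outcomes$true == 1 & outcomes$predicted == -1),
    tn = sum(outcomes$true == -1 & outcomes$predicted == -1),
    fp = sum(outcomes$true == -1 & outcomes$predicted == 1),
    decisions = outcomes$decision,
    labels = outcomes$true)
}

#' Misclassification overlap between two feature sets
#'
#' Within one group, takes the subjects misclassified under feature set A,
#' intersects with those misclassified under feature set B, and reports the
#' intersection as an integer percentage of A's misclassified set.
#'
#' @param outcomes_a,outcomes_b Fold outcome data.frames (or
#'   [run_nested_loocv()] results) over the same subjects.
#' @param group +1 or -1: which true group to restrict to.
#' @return Object of class `overlap_summary`: `n_missed_a`, `n_missed_b`,
#'   `n_overlap`, `percentage` (half-up integer), `missed_a`, `missed_b`.
#' @export
misclassification_overlap <- function(outcomes_a, outcomes_b, group) {
  a <- if (inherits(outcomes_a, "nested_loocv")) outcomes_a$outcomes else outcomes_a
  b <- if (inherits(outcomes_b, "nested_loocv")) outcomes_b$outcomes else outcomes_b
  if (!setequal(a$subject_id, b$subject_id))
    stop("the two outcome sets cover different subjects", call. = FALSE)
  if (!group %in% c(-1, 1)) stop("group must be +1 or -1", call. = FALSE)
  missed_a <- a$subject_id[a$true == group & a$predicted != a$true]
  missed_b <- b$subject_id[b$true == group & b$predicted != b$true]
  ov <- intersect(missed_a, missed_b)
  pct <- if (length(missed_a) == 0) NA_real_
         else round_half_up(100 * length(ov) / length(missed_a))
  structure(list(group = group,
                 n_missed_a = length(missed_a),
                 n_missed_b = length(missed_b),
                 n_overlap = length(ov),
                 percentage = pct,
                 missed_a = missed_a, missed_b = missed_b),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "<overlap_summary> group %+d: %d of %d A-misclassified also missed by B (%s%%)\n",
    x$group, x$n_overlap, x$n_missed_a,
    ifelse(is.na(x$percentage), "NA", x$percentage)))
  invisible(x)
}

#' Compare correctly vs incorrectly classified subjects on covariates
#'
#' Per variable: pooled-variance two-sample t between the incorrectly and
#' correctly classified subjects (in that order, so a positive t means the
#' misclassified mean is larger), two-sided p from the central t
#' distribution with df = n1 + n2 - 2, no multiplicity correction.
#' Variables with a subgroup smaller than 2 non-missing values, or zero
#' pooled variance, are skipped with a flag.
#'
#' @param records Subject table (rows aligned with `correct`).
#' @param correct Logical: was each subject correctly classified?
#' @param variables Character vector of numeric column names to test.
#' @return Data.frame: one row per variable with subgroup n/mean/SD, `t`,
#'   `p`, `df`, and `skipped` (with a `reason` attribute-free column).
#' @export
subgroup_comparison <- function(records, correct,
                                variables = c("age", "iq", "pclr_total", "fwd",
                                              "ptsd", "n_substance_dep",
                                              "incarceration_years")) {
  if (nrow(records) != length(correct))
    stop("correct flags must align with the record rows", call. = FALSE)
  rows <- lapply(variables, function(v) {
    if (!v %in% names(records))
      stop(sprintf("variable '%s' not in records", v), call. = FALSE)
    x_inc <- records[[v]][!correct]
    x_cor <- records[[v]][correct]
    x_inc <- x_inc[!is.na(x_inc)]
    x_cor <- x_cor[!is.na(x_cor)]
    n1 <- length(x_inc); n2 <- length(x_cor)
    out <- data.frame(
      variable = v,
      n_incorrect = n1, mean_incorrect = if (n1) mean(x_inc) else NA_real_,
      sd_incorrect = if (n1 > 1) sd(x_inc) else NA_real_,
      n_correct = n2, mean_correct = if (n2) mean(x_cor) else NA_real_,
      sd_correct = if (n2 > 1) sd(x_cor) else NA_real_,
      t = NA_real_, df = NA_integer_, p = NA_real_,
      skipped = FALSE, stringsAsFactors = FALSE)
    if (n1 < 2 || n2 < 2) {
      out$skipped <- TRUE
      return(out)
    }
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(x_inc) + (n2 - 1) * var(x_cor)) / df
    if (sp2 == 0) {
      out$skipped <- TRUE
      return(out)
    }
    tt <- (mean(x_inc) - mean(x_cor)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    out$t <- tt
    out$df <- df
    out$p <- 2 * pt(-abs(tt), df)
    out
  })
  do.call(rbind, rows)
}
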