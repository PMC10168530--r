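#!/usr/bin/env Rscript
# Stage 3 — classification rates, misclassification overlap, and subgroup
# comparisons.
#
# Reduces each metric's fold log to sensitivity / specificity / point AUC,
# computes the pairwise overlap of misclassified subjects between metrics
# within each group, and compares correctly vs incorrectly classified
# subjects on the cohort covariates (pooled two-sample t, uncorrected).

suppressPackageStartupMessages(library(dmriclass))

cls_dir <- "results/classify"
out_dir <- "results/evaluate"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

subjects <- read_subjects_tsv("results/data/FA/subjects.tsv")
metrics <- c("FA", "ODI", "Viso")
folds <- lapply(metrics, function(m)
  read_folds_tsv(file.path(cls_dir, m, "folds.tsv")))
names(folds) <- metrics

cat("classification rates (%):\n")
rates <- data.frame(feature = metrics, auc = NA, sensitivity = NA,
                    specificity = NA)
for (i in seq_along(metrics)) {
  s <- summarize_outcomes(folds[[i]])
  write_summary_json(s, file.path(out_dir, paste0("summary_", metrics[i], ".json")))
  rates[i, 2:4] <- c(s$point_auc, s$sensitivity, s$specificity)
  cat(sprintf("  %-4s AUC %6.2f  sens %6.2f  spec %6.2f  (rank AUC %6.2f)\n",
              metrics[i], s$point_auc, s$sensitivity, s$specificity, s$rank_auc))
}
write.table(rates, file.path(out_dir, "classification_rates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("misclassification overlap vs FA (share of FA-missed also missed):\n")
ov_rows <- list()
for (m in c("ODI", "Viso")) for (g in c(1, -1)) {
  ov <- misclassification_overlap(folds$FA, folds[[m]], group = g)
  ov_rows[[paste(m, g)]] <- data.frame(
    other = m, group = g, n_missed_fa = ov$n_missed_a,
    n_overlap = ov$n_overlap, percentage = ov$percentage)
  cat(sprintf("  FA vs %-4s group %+d: %d of %d (%s%%)\n",
              m, g, ov$n_overlap, ov$n_missed_a, ov$percentage))
}
write.table(do.call(rbind, ov_rows), file.path(out_dir, "overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# correct vs incorrect subgroup comparisons within each group, FA classifier
fa <- folds$FA[match(subjects$subject_id, folds$FA$subject_id), ]
correct <- fa$predicted == fa$true
for (g in c(1, -1)) {
  sel <- subjects$group == g
  vars <- c("age", "iq", "pclr_total", "fwd", "ptsd", "n_substance_dep",
            "incarceration_years")
  if (g == 1) vars <- c(vars, "n_tbis", "years_since_first_tbi",
                        "years_since_last_tbi")
  tab <- subgroup_comparison(subjects[sel, ], correct[sel], variables = vars)
  fn <- file.path(out_dir, sprintf("comparison_group%+d.tsv", g))
  write.table(tab, fn, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- tab$variable[!tab$skipped & tab$p < 0.05]
  cat(sprintf("group %+d: %d/%d correct; covariates at p<0.05: %s\n",
              g, sum(correct[sel]), sum(sel),
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
}
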