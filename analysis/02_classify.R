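#!/usr/bin/env Rscript
# Stage 2 — mask, residualize, and run the nested leave-one-out SVM.
#
# For each metric: build the white-matter mask by thresholding the mean FA
# image at 0.20 (the FA-derived mask is reused for ODI/Viso), regress age
# out of every masked voxel across all subjects, then run nested LOOCV over
# the (solver x C) grid — per outer fold an inner LOOCV picks the
# maximum-AUC configuration, voxels are re-screened at |t| >= 2 on the
# training rows, and the held-out subject is predicted. Writes folds.tsv
# and selection.json per metric.

suppressPackageStartupMessages(library(dmriclass))

data_dir <- "results/data"
out_dir <- "results/classify"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

subjects <- read_subjects_tsv(file.path(data_dir, "FA", "subjects.tsv"))
fa_stack <- read_metric_stack(file.path(data_dir, "FA", "stack.nii.gz"),
                              subjects, metric_name = "FA")
wm_mask <- build_wm_mask(fa_stack, threshold = 0.20)
cat(sprintf("WM mask: %d of %d voxels at mean-FA >= 0.20\n",
            sum(wm_mask$keep), length(wm_mask$keep)))

for (metric in c("FA", "ODI", "Viso")) {
  stack <- read_metric_stack(file.path(data_dir, metric, "stack.nii.gz"),
                             subjects, metric_name = metric, mask = wm_mask)
  resid <- residualize_age(stack, subjects$age)
  t0 <- Sys.time()
  fit <- run_nested_loocv(resid, subjects$group)
  el <- as.numeric(Sys.time() - t0, units = "secs")
  mdir <- file.path(out_dir, metric)
  dir.create(mdir, showWarnings = FALSE)
  write_folds_tsv(fit, file.path(mdir, "folds.tsv"))
  sel <- modal_configuration(fit)
  write_summary_json(sel, file.path(mdir, "selection.json"))
  write_run_config(list(seed = NA, metric = metric, mask_threshold = 0.20,
                        residualization = "all-subject age regression",
                        grid = "LS/SMO x {0.05,0.1,0.5,1,5,10} x t=2.0"),
                   file.path(mdir, "config.json"))
  cat(sprintf("%-4s: %d folds in %.1fs; modal config %s C=%g t=%g\n",
              metric, nrow(fit$outcomes), el,
              sel$modal$solver, sel$modal$C, sel$modal$t_threshold))
}
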