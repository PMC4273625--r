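#!/usr/bin/env Rscript
# Generate the synthetic study cohort and write the panels out as TSV, the
# format the pipeline consumes for real recordings.
source("analysis/00_config.R")

panels <- generate_cohort(cohort_config)
truth <- planted_truth(cohort_config)

panel_dir <- file.path(scratch_dir, "panels")
dir.create(panel_dir, showWarnings = FALSE, recursive = TRUE)
for (p in panels) {
  write_matrix_tsv(p$values, file.path(panel_dir, paste0(p$subject_id, ".tsv")))
}
write_json_report(list(
  n_subjects = cohort_config$n_subjects,
  n_rois = cohort_config$n_rois,
  n_timepoints = cohort_config$n_timepoints,
  dt = cohort_config$dt,
  bands = cohort_config$bands,
  hub_rois = cohort_config$hub_rois,
  coupling_order = truth$coupling_order
), file.path(results_dir, "cohort.json"))

cat(sprintf("wrote %d panels (%d x %d, dt = %g s) to %s\n",
            length(panels), nrow(panels[[1]]$values),
            ncol(panels[[1]]$values), cohort_config$dt, panel_dir))
cat("planted coupling order (strongest first):",
    paste(truth$coupling_order, collapse = " > "), "\n")
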