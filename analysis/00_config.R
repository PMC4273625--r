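# Shared configuration for the analysis scripts: one synthetic study cohort
# at the acquisition geometry of the resting-state protocol (87 ROIs, 610
# volumes at TR = 2 s), analyzed in the two signature bands.
library(freqnet)

cohort_config <- generator_config(n_subjects = 16)
study_bands <- list(vlf = band(0.01, 0.03), lf = band(0.07, 0.09))
sparsity_grid <- seq(0.05, 0.25, by = 0.05)
results_dir <- "results"
scratch_dir <- "scratch/analysis"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(scratch_dir, showWarnings = FALSE, recursive = TRUE)
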