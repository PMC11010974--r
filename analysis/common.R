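# Shared settings for the analysis drivers. The cohort mirrors the study
# design (12 CR + 9 AD patients, per-patient event counts spanning two
# orders of magnitude, cap 1000 cells/patient, perplexity 70, 3000
# iterations); total event counts are kept desk-sized.

library(hspcmap)

out_dir <- "results/run"
fig_dir <- "results/figures"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

study_seed <- 20240328L

study_spec <- cohort_spec(
  n_cr = 12, n_ad = 9,
  cells_per_patient = c(129, 8000),
  cd34_fraction = 0.2,
  seed = study_seed)

study_config <- load_config()
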