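#!/usr/bin/env Rscript
# Stage 1 — simulate a synthetic cohort of 12 CR and 9 AD patients and
# write one FCS 3.1 file per patient. The AD group's CD34+ compartment is
# enriched for CD38- and CD45RA+/CD123+/PD-L1-high leukemia-related
# populations.

source("analysis/common.R")

run_pipeline(out_dir, study_config, study_spec, stages = "simulate",
             seed = study_seed)

meta <- read.csv(file.path(out_dir, "simulate", "metadata.csv"))
cat(sprintf("simulated %d patients (%d CR, %d AD)\n", nrow(meta),
            sum(meta$group == "CR"), sum(meta$group == "AD")))
cat(sprintf("events per patient: %d to %d (median %d)\n",
            min(meta$n_events), max(meta$n_events),
            as.integer(median(meta$n_events))))
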