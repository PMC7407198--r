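#!/usr/bin/env Rscript

# Step 1 — simulate a synthetic surgical cohort.
#
# The study design: three patient groups (6 primary TKA, 5 aseptic TKR,
# 6 septic TKR), seven tissue samples per patient (four ATL locations,
# three RTL locations), 30 analytes per sample. The default generative
# effects encode the reported qualitative trends (cytokines highest in
# septic revision except IL-10/IL-12p70; phosphoproteins highest in
# primary except the pro-apoptotic trio). Absolute scales are
# illustrative: the underlying study deposits no raw concentrations.

suppressMessages(library(radnet))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- cohort_config(seed = 101L)
write_cohort_config(cfg, file.path(out_dir, "cohort_config.yml"))

records <- generate_cohort(cfg)
write_panel_table(records, file.path(out_dir, "cohort.csv"))

covariates <- generate_covariates(records, seed = 102L)
readr::write_csv(covariates, file.path(out_dir, "covariates.csv"))

cat(sprintf("simulated %d records for %d patients (%d censored, %d injected outliers)\n",
            nrow(records), length(unique(records$patient_id)),
            sum(records$qc != "ok"), sum(records$outlier)))
cat(sprintf("wrote %s, %s, %s\n",
            file.path(out_dir, "cohort.csv"),
            file.path(out_dir, "cohort_config.yml"),
            file.path(out_dir, "covariates.csv")))
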