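#!/usr/bin/env Rscript

# Step 2 — quality control and preprocessing.
#
# Fixed stage order: omit readings outside the quantitation limits, remove
# 1.5xIQR outliers per analyte x group x depth x location, average the
# locations within each depth, then scale every analyte to its global
# maximum so all six networks share one normalized [0, 1] scale.

suppressMessages(library(radnet))

out_dir <- "results"
records <- read_panel_table(file.path(out_dir, "cohort.csv"))

pre <- preprocess_cohort(records)
write_qc_report(pre$qc,
                path_txt = file.path(out_dir, "qc_report.txt"),
                path_json = file.path(out_dir, "qc_report.json"))
readr::write_csv(pre$normalized, file.path(out_dir, "normalized_responses.csv"))

cat(sprintf("censored: %d, outliers removed: %d, entries imputed: %d\n",
            pre$qc$n_censored, pre$qc$n_outliers_removed, pre$qc$n_imputed))
for (key in names(pre$matrices)) {
  m <- pre$matrices[[key]]
  cat(sprintf("  %-12s %d nodes x %d replicates\n", key,
              length(m$nodes), m$n_replicates))
}
cat(sprintf("wrote %s and %s\n", file.path(out_dir, "qc_report.txt"),
            file.path(out_dir, "normalized_responses.csv")))
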