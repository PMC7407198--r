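#!/usr/bin/env Rscript

# Step 4 — conventional comparisons alongside the network analysis.
#
# Per analyte: two-way (group x depth) fixed-effects ANOVA with Type II
# sums of squares and Bonferroni post-tests over the nine plotted
# contrasts. Then the confounder screen: Pearson correlations of age, sex
# (0/1 indicator), and BMI against every analyte, Bonferroni-corrected
# over the 90-pair family. The synthetic covariates are generated
# independently of the analytes, so the screen's expected finding is
# negative.

suppressMessages(library(radnet))

out_dir <- "results"
records <- read_panel_table(file.path(out_dir, "cohort.csv"))
covariates <- readr::read_csv(file.path(out_dir, "covariates.csv"),
                              show_col_types = FALSE)

avg <- depth_average(filter_outliers(drop_censored(records)))
stats <- anova_all_analytes(avg)

terms <- dplyr::bind_rows(lapply(stats, function(s) {
  dplyr::mutate(s$terms, analyte = s$analyte, .before = 1)
}))
posthoc <- dplyr::bind_rows(lapply(stats, function(s) {
  dplyr::mutate(s$posthoc, analyte = s$analyte, .before = 1)
}))
readr::write_csv(terms, file.path(out_dir, "anova_terms.csv"))
readr::write_csv(posthoc, file.path(out_dir, "anova_posthoc.csv"))

flagged <- posthoc[posthoc$flagged, ]
cat(sprintf("ANOVA: %d of %d analytes have at least one Bonferroni-flagged contrast\n",
            length(unique(flagged$analyte)), length(stats)))
top <- head(flagged[order(flagged$p_adj), ], 8)
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-12s %-26s adj p = %.2e\n",
              top$analyte[i], top$comparison[i], top$p_adj[i]))
}

screen <- pearson_confounder_screen(covariates, avg)
readr::write_csv(screen, file.path(out_dir, "confounder_screen.csv"))
n_sig <- sum(screen$significant, na.rm = TRUE)
cat(sprintf("confounder screen: %d of %d covariate x analyte pairs significant after Bonferroni\n",
            n_sig, attr(screen, "m")))
cat(sprintf("wrote anova_terms.csv, anova_posthoc.csv, confounder_screen.csv under %s/\n",
            out_dir))
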