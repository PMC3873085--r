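#!/usr/bin/env Rscript
# Stage 2 preamble: factor-analysis feature selection on the cases of
# interest.
#
# The clustering model's parameter count grows as K(d+2)(d+1)/2, so the
# 10 exposure features are reduced first: check sampling adequacy (KMO,
# Bartlett sphericity), keep principal factors with eigenvalue > 1, rotate
# them (varimax) and keep the features with a rotated loading above 0.4.

suppressPackageStartupMessages(library(comorbscreen))

out_dir <- "results/analysis"
cohort <- read_subject_table(file.path(out_dir, "subjects_screened.tsv"))
features <- subjects_to_features(cohort)
norm <- min_max_normalize(features)
interest <- cohort$group == "case" & cohort$of_interest == 1

fs <- run_factor_selection(norm$matrix[interest, ], cutoff = 0.4)

cat(sprintf("factor analysis over %d cases of interest\n", sum(interest)))
cat(sprintf("KMO sampling adequacy: %.3f (threshold 0.5)\n", fs$kmo))
cat(sprintf("Bartlett sphericity: chi2 = %.1f (df %d), p = %.3g\n",
            fs$bartlett_stat, fs$bartlett_df, fs$bartlett_p))
cat("eigenvalues:", paste(sprintf("%.3f", fs$eigenvalues), collapse = " "), "\n")
cat(sprintf("%d factor(s) retained (eigenvalue > 1)\n", fs$n_factors))
cat("selected features:", paste(fs$selected_features, collapse = ", "), "\n")
if (length(fs$dropped) > 0)
  cat("columns excluded as constant/collinear:",
      paste(fs$dropped, collapse = ", "), "\n")

report <- data.frame(feature = rownames(fs$rotated_loadings),
                     round(fs$rotated_loadings, 4))
colnames(report)[-1] <- paste0("factor", seq_len(fs$n_factors))
report$selected <- as.integer(report$feature %in% fs$selected_features)
write.table(report, file.path(out_dir, "factor_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(c(sprintf("kmo\t%.6f", fs$kmo),
             sprintf("bartlett_stat\t%.6f", fs$bartlett_stat),
             sprintf("bartlett_p\t%.6g", fs$bartlett_p),
             sprintf("n_factors\t%d", fs$n_factors),
             paste0("selected\t", paste(fs$selected_features, collapse = ","))),
           file.path(out_dir, "factor_summary.tsv"))
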