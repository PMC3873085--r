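#!/usr/bin/env Rscript
# Stage 1: likelihood-ratio screening of cases.
#
# Fit one variable-bandwidth kernel density on the (min-max normalized)
# case exposure vectors and one on the control vectors, and flag as "of
# interest" every case whose case/control density ratio exceeds 1: its
# exposure profile is more typical of cases than of controls.

suppressPackageStartupMessages(library(comorbscreen))

out_dir <- "results/analysis"
cohort <- read_subject_table(file.path(out_dir, "subjects.tsv"))
features <- subjects_to_features(cohort)
norm <- min_max_normalize(features)
is_case <- cohort$group == "case"

scr <- select_of_interest(norm$matrix[is_case, ], norm$matrix[!is_case, ],
                          k = 10, beta = 1, threshold = 1)

cohort$of_interest <- 0L
cohort$of_interest[is_case] <- as.integer(scr$selected)
write_subject_table(cohort, file.path(out_dir, "subjects_screened.tsv"))
write.table(data.frame(subject_id = cohort$subject_id[is_case],
                       ratio = scr$ratios,
                       of_interest = as.integer(scr$selected)),
            file.path(out_dir, "ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("screened %d cases against %d controls (k = 10, beta = 1)\n",
            sum(is_case), sum(!is_case)))
cat(sprintf("cases of interest: %d of %d (%.1f%%) at ratio threshold 1\n",
            sum(scr$selected), sum(is_case),
            proportion(sum(scr$selected), sum(is_case))))
cat(sprintf("ratio quartiles: %.3g / %.3g / %.3g\n",
            quantile(scr$ratios, 0.25), median(scr$ratios),
            quantile(scr$ratios, 0.75)))
# how well the screen enriches for the planted high-exposure subcluster
hi <- cohort$true_cluster[is_case] == "high_exposure"
cat(sprintf("planted high-exposure cases selected: %d of %d\n",
            sum(scr$selected & hi), sum(hi)))
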