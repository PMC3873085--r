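#!/usr/bin/env Rscript
# Co-morbidity and demographics statistics over the three partitions of the
# analysis: case vs matched control, cases of interest vs remaining cases,
# and mixture cluster 1 vs cluster 0.  Each outcome is summarized as a 2x2
# odds ratio with Woolf 95% CI; demographics rows use chi-square (counts)
# or Welch t (exposure means among utilizers).

suppressPackageStartupMessages(library(comorbscreen))

out_dir <- "results/analysis"
cohort <- read_subject_table(file.path(out_dir, "subjects_clustered.tsv"))
cases <- cohort[cohort$group == "case", ]
interest <- cohort[!is.na(cohort$cluster), ]

partitions <- list(
  case_control = list(data = cohort, part = cohort$group,
                      levels = c("case", "control")),
  interest_remaining = list(
    data = cases,
    part = ifelse(cases$of_interest == 1, "of_interest", "remaining"),
    levels = c("of_interest", "remaining")),
  cluster1_cluster0 = list(
    data = interest, part = paste0("cluster", interest$cluster),
    levels = c("cluster1", "cluster0"))
)

for (nm in names(partitions)) {
  p <- partitions[[nm]]
  demog <- build_demographics(p$data, p$part, group_levels = p$levels)
  ors <- outcome_odds_table(p$data, p$part, group_levels = p$levels)
  write.table(demog, file.path(out_dir, paste0("demographics_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ors, file.path(out_dir, paste0("odds_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("\n== %s (%s vs %s) ==\n", nm, p$levels[1], p$levels[2]))
  for (i in seq_len(nrow(ors)))
    cat(sprintf("  %-18s OR %5.2f (95%% CI %.2f-%.2f)%s\n",
                ors$outcome[i], round_half_up(ors$or[i], 2),
                ors$ci_low[i], ors$ci_high[i],
                if (ors$p_value[i] < 0.05) " *" else ""))
}
cat("\ntables written under", out_dir, "\n")
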