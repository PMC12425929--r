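#!/usr/bin/env Rscript
# Step 3: aggregate per-trial measures into the cell-level analysis table.
#
# One row per participant x vowel x condition cell (24 x 4 x 2 = 192 rows):
# trial-to-trial variability (TTV; RMS Euclidean deviation of per-trial
# window-mean Mel F1/F2 from the cell's grand average), within-trial
# variability (WTV; RMS of within-window Mel SDs), their natural logs, mean
# duration and intensity, and the cell centroid. Also writes the
# inter-vowel distance per participant x condition.

suppressPackageStartupMessages(library(vowelvar))

measures <- read.csv("scratch/trial_measures.csv", stringsAsFactors = FALSE)
tab <- build_analysis_table(measures)
cat("analysis table:", nrow(tab), "cells (expect 192)\n")
write.csv(tab, "results/03_analysis_table.csv", row.names = FALSE)

dist_tab <- inter_vowel_distance_table(tab)
write.csv(dist_tab, "results/03_intervowel_distance.csv", row.names = FALSE)

# quick look: cell-mean TTV per group x condition (Mel)
print(aggregate(ttv_mel ~ group + condition, tab, mean))
print(aggregate(wtv_mel ~ group + condition, tab, mean))
print(aggregate(inter_vowel_distance_mel ~ group + condition, dist_tab, mean))
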