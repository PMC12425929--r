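#!/usr/bin/env Rscript
# Step 4: statistical inference on the cell-level analysis table.
#
# Fits the balanced split-plot mixed ANOVA (vowel x condition x group fixed,
# participant random intercept) to log TTV, log WTV, duration and intensity;
# computes Tukey-adjusted post-hocs (vowel family, group x condition cells),
# the condition simple effects within each group, and the participant-level
# correlations between log WTV and log TTV per group x condition. Writes CSV
# tables plus a single JSON report.

suppressPackageStartupMessages(library(vowelvar))

tab <- read.csv("results/03_analysis_table.csv", stringsAsFactors = FALSE)
res <- run_variability_analysis(tab)

for (resp in names(res$models)) {
  m <- res$models[[resp]]
  write.csv(m$anova, sprintf("results/04_anova_%s.csv", resp),
            row.names = FALSE)
  cat("\n==", resp, "==\n")
  print(transform(m$anova, F = round(F, 3), p = signif(p, 3))[
    , c("effect", "df_num", "df_den", "F", "p")], row.names = FALSE)
}

primary <- res$models$log_ttv
write.csv(primary$posthoc_vowel, "results/04_posthoc_vowel_log_ttv.csv",
          row.names = FALSE)
write.csv(primary$posthoc_group_condition,
          "results/04_posthoc_group_condition_log_ttv.csv", row.names = FALSE)
write.csv(primary$simple_effects_condition,
          "results/04_simple_effects_log_ttv.csv", row.names = FALSE)

cat("\nlog TTV condition simple effects (DAF - NAF within group):\n")
print(transform(primary$simple_effects_condition,
                estimate = round(estimate, 3), t = round(t, 2),
                p_adj = signif(p_adj, 3))[
  , c("contrast", "estimate", "t", "df", "p_adj")], row.names = FALSE)

cat("\nWTV-TTV correlations (participant level):\n")
cors <- do.call(rbind, lapply(names(res$wtv_ttv_correlations), function(k) {
  x <- res$wtv_ttv_correlations[[k]]
  data.frame(cell = k, r = round(x$r, 3), p = round(x$p, 3), n = x$n)
}))
print(cors, row.names = FALSE)
write.csv(cors, "results/04_wtv_ttv_correlations.csv", row.names = FALSE)

write_report_json(res, "results/04_report.json", seed = 20260924L)
cat("\nreport written to results/04_report.json\n")
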