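#!/usr/bin/env Rscript
# Step 1: simulate the synthetic cohort and write it to disk as WAV files
# plus an annotation table.
#
# The cohort mirrors the study design: 12 adults who stutter (AWS) and 12
# matched nonstuttering adults (ANS), each producing 96 trials per auditory
# feedback condition (NAF and 100-ms DAF), evenly split over the four front
# vowels /i ih eh ae/ (24 trials per vowel per condition), recorded at
# 44,100 Hz. Trial-to-trial Mel formant dispersion is higher at baseline in
# the AWS group, and DAF shifts it in opposite directions in the two groups;
# DAF also lengthens vowels (x1.2) and raises intensity (+3 dB).
#
# Audio is written under scratch/ (large, regenerable); the annotation table
# and a design summary go to results/.

suppressPackageStartupMessages(library(vowelvar))

seed <- 20260924L
out_dir <- "scratch/dataset"
dir.create("results", showWarnings = FALSE)
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- cohort_config(seed = seed)
saveRDS(config, file.path("scratch", "cohort_config.rds"))

plan <- cohort_trial_plan(config)
cat(sprintf("cohort: %d trials (%d participants x 2 conditions x 4 vowels x %d)\n",
            nrow(plan), 2 * config$n_per_group,
            config$trials_per_vowel_per_condition))

# stream trial synthesis to keep memory flat
ann <- vector("list", nrow(plan))
t0 <- Sys.time()
for (i in seq_len(nrow(plan))) {
  trial <- synthesize_trial(plan[i, ], config)
  write_wav(trial$waveform$samples, trial$waveform$fs,
            file.path(out_dir, paste0(trial$meta$trial_id, ".wav")))
  ann[[i]] <- data.frame(
    trial_id = trial$meta$trial_id, participant = trial$meta$participant,
    group = trial$meta$group, condition = trial$meta$condition,
    vowel = trial$meta$vowel,
    wav_path = paste0(trial$meta$trial_id, ".wav"),
    onset_s = trial$onset, offset_s = trial$offset, excluded = 0L)
  if (i %% 500 == 0) cat("  synthesized", i, "trials\n")
}
ann <- do.call(rbind, ann)
write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)

summary_tab <- as.data.frame(table(group = ann$group, condition = ann$condition,
                                   vowel = ann$vowel))
write.csv(summary_tab, "results/01_design_summary.csv", row.names = FALSE)
cat(sprintf("wrote %d WAVs + annotations to %s in %.1f min\n",
            nrow(ann), out_dir,
            as.numeric(difftime(Sys.time(), t0, units = "mins"))))
cat("design cells are balanced:",
    all(summary_tab$Freq ==
          config$n_per_group * config$trials_per_vowel_per_condition), "\n")
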