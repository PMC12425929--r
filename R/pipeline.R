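# Pipeline drivers: connect synthesis -> tracking -> segmentation -> metrics
# -> statistics. Trials that fail a stage (degenerate tracking, too few
# window frames, silent spans) are excluded and logged with the reason, and
# the exclusion table is reported per group x condition.

#' Measure one synthetic trial
#'
#' @param trial A synthetic trial from [synthesize_trial()].
#' @param tracker_cfg A [tracker_config()]; ignored when `use_truth = TRUE`.
#' @param use_truth If `TRUE`, compute measures from the ground-truth formant
#'   track instead of running the LPC tracker (for oracle comparisons).
#' @param window_s Feedforward window length in s.
#' @return One-row data frame of [trial_measures()].
#' @export
measure_synth_trial <- function(trial, tracker_cfg = tracker_config(),
                                use_truth = FALSE, window_s = 0.050) {
  span <- vowel_span(trial$onset, trial$offset, source = "annotation")
  track <- if (use_truth) {
    tt <- trial$truth_track
    list(frame_times = tt$frame_times, F = tt$F, B = tt$B,
         flagged = rep(FALSE, length(tt$frame_times)), candidates = NULL)
  } else {
    track_formants(trial$waveform, tracker_cfg)
  }
  trial_measures(track, span, w = trial$waveform, meta = trial$meta,
                 window_s = window_s)
}

#' Measure an entire cohort, streaming trial by trial
#'
#' Draws the cohort plan, synthesizes each trial, tracks and measures it,
#' and discards the audio, so memory stays flat for the full 4,608-trial
#' design. Failing trials are excluded with a logged reason.
#'
#' @param config A [cohort_config()].
#' @param tracker_cfg A [tracker_config()].
#' @param use_truth Measure from ground-truth tracks instead of the tracker.
#' @param window_s Feedforward window length in s.
#' @param progress Print progress every 500 trials.
#' @return List with `measures` (per-trial data frame), `exclusions`
#'   (trial_id, group, condition, reason) and `plan`.
#' @export
measure_cohort <- function(config, tracker_cfg = tracker_config(),
                           use_truth = FALSE, window_s = 0.050,
                           progress = FALSE) {
  plan <- cohort_trial_plan(config)
  measures <- vector("list", nrow(plan))
  exclusions <- list()
  for (i in seq_len(nrow(plan))) {
    res <- tryCatch({
      trial <- synthesize_trial(plan[i, ], config)
      measure_synth_trial(trial, tracker_cfg, use_truth = use_truth,
                          window_s = window_s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        trial_id = plan$trial_id[i], group = plan$group[i],
        condition = plan$condition[i], reason = conditionMessage(res),
        stringsAsFactors = FALSE
      )
    } else {
      measures[[i]] <- res
    }
    if (progress && i %% 500 == 0) {
      message("measured ", i, "/", nrow(plan), " trials")
    }
  }
  list(
    measures = do.call(rbind, measures),
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(trial_id = character(), group = character(),
                 condition = character(), reason = character()),
    plan = plan
  )
}

#' Measure a dataset on disk (WAV files + annotation CSV)
#'
#' The analysis path for real recordings: vowel bounds come from the
#' annotation table (`source = "annotation"`), trials with `excluded = 1`
#' are skipped, and tracking/windowing failures are excluded with a reason.
#'
#' @param dataset_dir Directory containing `annotations.csv` and the WAVs.
#' @param tracker_cfg A [tracker_config()].
#' @param window_s Feedforward window length in s.
#' @return List with `measures` and `exclusions` data frames.
#' @export
analyze_dataset <- function(dataset_dir, tracker_cfg = tracker_config(),
                            window_s = 0.050) {
  ann <- read_annotations(file.path(dataset_dir, "annotations.csv"))
  measures <- vector("list", nrow(ann))
  exclusions <- list()
  for (i in seq_len(nrow(ann))) {
    if (ann$excluded[i] != 0) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        trial_id = ann$trial_id[i], group = ann$group[i],
        condition = ann$condition[i], reason = "pre-excluded in annotations",
        stringsAsFactors = FALSE
      )
      next
    }
    res <- tryCatch({
      w <- read_wav(file.path(dataset_dir, ann$wav_path[i]))
      span <- vowel_span(ann$onset_s[i], ann$offset_s[i])
      track <- track_formants(w, tracker_cfg)
      trial_measures(track, span, w = w,
                     meta = list(trial_id = ann$trial_id[i],
                                 participant = ann$participant[i],
                                 group = ann$group[i],
                                 condition = ann$condition[i],
                                 vowel = ann$vowel[i]),
                     window_s = window_s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        trial_id = ann$trial_id[i], group = ann$group[i],
        condition = ann$condition[i], reason = conditionMessage(res),
        stringsAsFactors = FALSE
      )
    } else {
      measures[[i]] <- res
    }
  }
  list(
    measures = do.call(rbind, measures),
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(trial_id = character(), group = character(),
                 condition = character(), reason = character())
  )
}

#' Exclusion rates per group x condition
#'
#' @param exclusions Exclusion data frame from [measure_cohort()] /
#'   [analyze_dataset()].
#' @param plan The trial plan or annotation table (for denominators).
#' @return Data frame with `group`, `condition`, `n_trials`, `n_excluded`,
#'   `rate`.
#' @export
exclusion_summary <- function(exclusions, plan) {
  tot <- as.data.frame(table(group = plan$group, condition = plan$condition),
                       stringsAsFactors = FALSE)
  names(tot)[3] <- "n_trials"
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    out <- tot
    out$n_excluded <- 0
  } else {
    exc <- as.data.frame(table(group = exclusions$group,
                               condition = exclusions$condition),
                         stringsAsFactors = FALSE)
    names(exc)[3] <- "n_excluded"
    out <- merge(tot, exc, all.x = TRUE)
    out$n_excluded[is.na(out$n_excluded)] <- 0
  }
  out$rate <- out$n_excluded / out$n_trials
  out
}

#' Run the full statistical stage on an analysis table
#'
#' Fits the split-plot mixed ANOVA to each requested response, computes
#' Tukey post-hocs (vowel and group x condition families), the condition
#' simple effects within each group for the primary response, the
#' within-trial vs trial-to-trial variability correlations per group x
#' condition, and the inter-vowel distance descriptives.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @param responses Response columns to model.
#' @return Nested list of results, JSON-serializable via
#'   [write_report_json()].
#' @export
run_variability_analysis <- function(analysis_table,
                                     responses = c("log_ttv", "log_wtv",
                                                   "mean_duration_ms",
                                                   "mean_intensity_db")) {
  fits <- lapply(responses, function(resp) {
    fit <- fit_mixed_anova(analysis_table, resp)
    list(
      anova = fit$anova,
      variance_components = list(participant = fit$sigma_participant2,
                                 residual = fit$sigma_residual2),
      posthoc_vowel = posthoc_pairwise(fit, "vowel"),
      posthoc_group = posthoc_pairwise(fit, "group"),
      posthoc_group_condition = posthoc_pairwise(fit, "group_condition"),
      simple_effects_condition = simple_effects_condition_within_group(fit)
    )
  })
  names(fits) <- responses

  groups <- unique(analysis_table$group)
  conditions <- unique(analysis_table$condition)
  cors <- list()
  for (g in groups) for (cnd in conditions) {
    cors[[paste(g, cnd, sep = "_")]] <-
      correlate_wtv_ttv(analysis_table, g, cnd)
  }

  dist_tab <- inter_vowel_distance_table(analysis_table)
  dist_means <- stats::aggregate(
    inter_vowel_distance_mel ~ group + condition, data = dist_tab, FUN = mean)

  list(models = fits, wtv_ttv_correlations = cors,
       inter_vowel_distance = list(by_participant = dist_tab,
                                   means = dist_means))
}

#' Write an analysis report as JSON
#'
#' @param results Output of [run_variability_analysis()].
#' @param path Output path.
#' @param seed Seed used for the run (recorded in the report).
#' @param extra Optional named list merged into the report (e.g. exclusion
#'   summary, config description).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(results, path, seed = NULL, extra = list()) {
  report <- c(list(seed = seed), results, extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
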