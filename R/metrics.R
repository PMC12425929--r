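# Dependent variables: per-trial window measures, trial-to-trial variability
# (TTV), within-trial variability (WTV), inter-vowel distance, and the
# log-transformed cell-level analysis table.

#' Per-trial measures over the feedforward window
#'
#' Computes the window-mean and within-window SD of Mel-scaled F1 and F2
#' over the first `window_s` of the vowel, plus duration and intensity.
#'
#' @param track Formant track covering the vowel span (Hz).
#' @param span A vowel span.
#' @param w Waveform (for intensity); optional, `NA` intensity if missing.
#' @param meta Named list of trial identifiers carried into the output
#'   (e.g. participant, group, condition, vowel, trial_id).
#' @param window_s Analysis window length in s.
#' @return One-row data frame with `m1`, `m2` (Mel), `s1`, `s2` (Mel),
#'   `duration_ms`, `intensity_db`, `n_frames`, `n_flagged` and the metadata.
#' @export
trial_measures <- function(track, span, w = NULL, meta = list(),
                           window_s = 0.050) {
  win <- extract_window(track, span, window_s = window_s)
  mel1 <- hz_to_mel(win$F[, 1])
  mel2 <- hz_to_mel(win$F[, 2])
  out <- data.frame(
    m1 = mean(mel1), m2 = mean(mel2),
    s1 = stats::sd(mel1), s2 = stats::sd(mel2),
    duration_ms = vowel_duration(span),
    intensity_db = if (is.null(w)) NA_real_ else vowel_intensity(w, span),
    n_frames = length(win$frame_times),
    n_flagged = sum(win$flagged),
    stringsAsFactors = FALSE
  )
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}

#' Trial-to-trial formant variability of one cell
#'
#' For the trials of one participant x vowel x condition cell, subtracts the
#' cell's grand-average F1 and F2 from each trial's window-mean formants and
#' returns the root mean square of the per-trial Euclidean deviations:
#' \deqn{TTV = \sqrt{ \tfrac{1}{n} \sum_i (d_{1i}^2 + d_{2i}^2) }}
#' in Mel, where `d_ki = m_ki - center(m_k)`.
#'
#' @param trials Data frame with columns `m1`, `m2` (one row per trial).
#' @param center `"mean"` (grand average, the default) or `"median"`.
#' @return TTV in Mel.
#' @export
trial_to_trial_variability <- function(trials, center = c("mean", "median")) {
  center <- match.arg(center)
  n <- nrow(trials)
  if (is.null(n) || n < 2) {
    stop("trial_to_trial_variability: need at least 2 trials")
  }
  cfun <- if (center == "mean") mean else stats::median
  d1 <- trials$m1 - cfun(trials$m1)
  d2 <- trials$m2 - cfun(trials$m2)
  sqrt(mean(d1^2 + d2^2))
}

#' Within-trial formant variability of one cell
#'
#' Root mean square of the within-window F1 and F2 trajectory SDs over all
#' trials of a cell:
#' \deqn{WTV = \sqrt{ \tfrac{1}{2n} \sum_i (s_{1i}^2 + s_{2i}^2) }}
#' in Mel. Unlike TTV this pools the two formants' SDs directly, so it is
#' unaffected by between-trial spread.
#'
#' @param trials Data frame with columns `s1`, `s2`.
#' @return WTV in Mel.
#' @export
within_trial_variability <- function(trials) {
  n <- nrow(trials)
  if (is.null(n) || n < 1) stop("within_trial_variability: need >= 1 trial")
  if (any(!is.finite(c(trials$s1, trials$s2)))) {
    stop("within_trial_variability: non-finite within-trial SDs")
  }
  sqrt(sum(trials$s1^2 + trials$s2^2) / (2 * n))
}

#' Mean inter-vowel distance in the F1-F2 plane
#'
#' Mean of the 6 pairwise Euclidean distances among the four vowel centroids
#' of one participant x condition, in Mel (F1, F2) coordinates. A summary of
#' how distinct the vowels are.
#'
#' @param centroids Data frame with columns `vowel`, `c1`, `c2` (Mel);
#'   exactly one row per vowel, 4 vowels.
#' @param vowels The vowel labels that must be present.
#' @return Mean pairwise distance in Mel.
#' @export
inter_vowel_distance <- function(centroids,
                                 vowels = c("i", "ih", "eh", "ae")) {
  missing <- setdiff(vowels, centroids$vowel)
  if (length(missing) > 0) {
    stop("inter_vowel_distance: missing vowels: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(centroids) != length(vowels) || anyDuplicated(centroids$vowel)) {
    stop("inter_vowel_distance: need exactly one centroid per vowel")
  }
  mean(stats::dist(cbind(centroids$c1, centroids$c2)))
}

#' Build the cell-level analysis table
#'
#' Aggregates per-trial measures into one row per participant x vowel x
#' condition cell: TTV, WTV, their natural-log transforms (variability is
#' bounded below by zero, so logs are taken before linear modeling), mean
#' duration and intensity, and the cell centroid. Cells with zero
#' variability cannot be log-transformed and are dropped with a warning.
#'
#' @param measures Data frame of [trial_measures()] rows with columns
#'   `participant`, `group`, `condition`, `vowel`, `m1`, `m2`, `s1`, `s2`,
#'   `duration_ms`, `intensity_db`.
#' @param center Centering rule for TTV, see [trial_to_trial_variability()].
#' @return Data frame with one row per cell: `participant`, `group`,
#'   `condition`, `vowel`, `n_trials`, `ttv_mel`, `wtv_mel`, `log_ttv`,
#'   `log_wtv`, `mean_duration_ms`, `mean_intensity_db`, `centroid_f1_mel`,
#'   `centroid_f2_mel`.
#' @export
build_analysis_table <- function(measures, center = "mean") {
  if (is.null(measures) || nrow(measures) == 0) {
    stop("build_analysis_table: empty input")
  }
  req <- c("participant", "group", "condition", "vowel", "m1", "m2", "s1", "s2")
  missing <- setdiff(req, names(measures))
  if (length(missing)) {
    stop("build_analysis_table: missing columns: ",
         paste(missing, collapse = ", "))
  }
  key <- interaction(measures$participant, measures$vowel,
                     measures$condition, drop = TRUE)
  rows <- lapply(split(measures, key), function(cell) {
    data.frame(
      participant = cell$participant[1], group = cell$group[1],
      condition = cell$condition[1], vowel = cell$vowel[1],
      n_trials = nrow(cell),
      ttv_mel = trial_to_trial_variability(cell, center = center),
      wtv_mel = within_trial_variability(cell),
      mean_duration_ms = mean(cell$duration_ms),
      mean_intensity_db = mean(cell$intensity_db),
      centroid_f1_mel = mean(cell$m1), centroid_f2_mel = mean(cell$m2),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  zero <- tab$ttv_mel <= 0 | tab$wtv_mel <= 0
  if (any(zero)) {
    warning("build_analysis_table: dropping ", sum(zero),
            " cell(s) with zero variability (cannot be log-transformed)")
    tab <- tab[!zero, , drop = FALSE]
  }
  tab$log_ttv <- log(tab$ttv_mel)
  tab$log_wtv <- log(tab$wtv_mel)
  tab[, c("participant", "group", "condition", "vowel", "n_trials",
          "ttv_mel", "wtv_mel", "log_ttv", "log_wtv", "mean_duration_ms",
          "mean_intensity_db", "centroid_f1_mel", "centroid_f2_mel")]
}

#' Inter-vowel distances for every participant x condition
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @return Data frame with `participant`, `group`, `condition`,
#'   `inter_vowel_distance_mel`.
#' @export
inter_vowel_distance_table <- function(analysis_table) {
  key <- interaction(analysis_table$participant, analysis_table$condition,
                     drop = TRUE)
  rows <- lapply(split(analysis_table, key), function(cells) {
    data.frame(
      participant = cells$participant[1], group = cells$group[1],
      condition = cells$condition[1],
      inter_vowel_distance_mel = inter_vowel_distance(
        data.frame(vowel = cells$vowel, c1 = cells$centroid_f1_mel,
                   c2 = cells$centroid_f2_mel),
        vowels = unique(analysis_table$vowel)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
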