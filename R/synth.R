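# Source-filter vowel synthesis and cohort simulation.
#
# Audio is produced by passing an impulse-train glottal source through a
# cascade of second-order resonators (one per formant), the classical
# cascade synthesis model. Formant frequencies are held piecewise-constant
# over 5-ms blocks; the exact per-block values are recorded as the
# ground-truth formant track, which is what makes the synthesizer usable as
# an oracle for the LPC tracker.

#' Default vowel targets for the four front vowels
#'
#' Canonical adult-male American English formant values for /i/, /ɪ/, /ɛ/
#' and /æ/ (ASCII labels `"i"`, `"ih"`, `"eh"`, `"ae"`). F3 is 3010 Hz for
#' /i/ (whose F2 sits high, near 2300 Hz) and 2500 Hz otherwise; F4 is
#' 3500 Hz, bandwidths 80/120/160/200 Hz, f0 120 Hz.
#' Base durations give /æ/ the longest vowel and base intensity makes /i/
#' slightly quieter, matching the usual intrinsic vowel differences.
#'
#' @return A named list of vowel targets. Each target is a list with fields
#'   `label`, `F` (Hz, length 4), `B` (Hz, length 4), `f0` (Hz),
#'   `base_duration` (s) and `base_intensity` (dB offset).
#' @export
vowel_targets <- function() {
  mk <- function(label, f1, f2, f3, dur, intens) {
    list(label = label, F = c(f1, f2, f3, 3500), B = c(80, 120, 160, 200),
         f0 = 120, base_duration = dur, base_intensity = intens)
  }
  list(
    i  = mk("i",  270, 2290, 3010, 0.24, -2),
    ih = mk("ih", 390, 1990, 2550, 0.22,  0),
    eh = mk("eh", 530, 1840, 2480, 0.25,  0),
    ae = mk("ae", 660, 1720, 2410, 0.30,  0)
  )
}

validate_vowel_target <- function(target) {
  stopifnot(
    is.list(target), length(target$F) == 4, length(target$B) == 4,
    all(target$F > 0), all(target$B > 0), all(diff(target$F) > 0),
    target$f0 > 0, target$base_duration >= 0.1
  )
  invisible(target)
}

#' Cohort design configuration
#'
#' Describes the factorial design the generator emulates: 2 groups (AWS,
#' adults who stutter; ANS, adults who do not) of `n_per_group` participants,
#' 2 auditory feedback conditions (NAF, normal; DAF, 100-ms delayed), 4 front
#' vowels, `trials_per_vowel_per_condition` trials per cell.
#'
#' `sigma_trial` is a group-by-condition matrix of trial-to-trial Mel
#' dispersion: per-trial formant offsets are drawn independently per formant
#' with this SD (times a per-vowel scale making /i/ the most stable vowel).
#' The defaults encode the phenomenon under study: a higher stuttering-group
#' baseline, with delayed feedback increasing dispersion in the nonstuttering
#' group but decreasing it in the stuttering group (log-scale shifts of
#' +0.25/-0.25). Delayed feedback also lengthens vowels
#' (`daf_duration_factor`) and raises intensity (`daf_intensity_shift`), as
#' delayed feedback reliably does to speakers.
#'
#' @param n_per_group Participants per group.
#' @param trials_per_vowel_per_condition Trials per participant x vowel x
#'   condition cell (24 gives 96 trials per condition over the 4 vowels).
#' @param fs Audio sampling frequency in Hz.
#' @param sigma_trial 2x2 numeric matrix (rows `AWS`, `ANS`; columns `NAF`,
#'   `DAF`) of trial-to-trial Mel SDs.
#' @param sigma_within Within-trial formant drift SD in Mel.
#' @param vowel_sigma_scale Named per-vowel multiplier on `sigma_trial`.
#' @param vowel_within_scale Named per-vowel multiplier on `sigma_within`
#'   (making /æ/ the most variable within a trial).
#' @param daf_duration_factor Multiplicative vowel duration effect of DAF.
#' @param daf_intensity_shift Additive intensity effect of DAF in dB.
#' @param duration_jitter_sd SD of per-trial lognormal duration jitter.
#' @param intensity_jitter_sd SD of per-trial intensity jitter in dB.
#' @param vowel_targets Vowel target list, see [vowel_targets()].
#' @param seed Integer RNG seed; the whole cohort is deterministic given it.
#' @return A validated cohort configuration (list).
#' @export
cohort_config <- function(n_per_group = 12,
                          trials_per_vowel_per_condition = 24,
                          fs = 44100,
                          sigma_trial = matrix(
                            c(12 * exp(0.5), 12 * exp(0.25),
                              12,            12 * exp(0.25)),
                            nrow = 2, byrow = TRUE,
                            dimnames = list(c("AWS", "ANS"), c("NAF", "DAF"))),
                          sigma_within = 8,
                          vowel_sigma_scale = c(i = 0.8, ih = 1, eh = 1, ae = 1.15),
                          vowel_within_scale = c(i = 0.9, ih = 1, eh = 1, ae = 1.3),
                          daf_duration_factor = 1.2,
                          daf_intensity_shift = 3,
                          duration_jitter_sd = 0.05,
                          intensity_jitter_sd = 0.5,
                          vowel_targets = vowelvar::vowel_targets(),
                          seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    trials_per_vowel_per_condition = as.integer(trials_per_vowel_per_condition),
    fs = fs, sigma_trial = sigma_trial, sigma_within = sigma_within,
    vowel_sigma_scale = vowel_sigma_scale,
    vowel_within_scale = vowel_within_scale,
    daf_duration_factor = daf_duration_factor,
    daf_intensity_shift = daf_intensity_shift,
    duration_jitter_sd = duration_jitter_sd,
    intensity_jitter_sd = intensity_jitter_sd,
    vowel_targets = vowel_targets, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_per_group >= 1, cfg$trials_per_vowel_per_condition >= 1,
    cfg$fs > 0, is.matrix(cfg$sigma_trial),
    all(rownames(cfg$sigma_trial) == c("AWS", "ANS")),
    all(colnames(cfg$sigma_trial) == c("NAF", "DAF")),
    all(cfg$sigma_trial >= 0), cfg$sigma_within >= 0,
    cfg$daf_duration_factor > 0
  )
  if (!all(names(cfg$vowel_targets) %in% names(cfg$vowel_sigma_scale))) {
    stop("cohort_config: vowel_sigma_scale must name every vowel target")
  }
  for (tg in cfg$vowel_targets) validate_vowel_target(tg)
  invisible(cfg)
}

# Orthonormal zero-mean drift basis on [0, 1] (shifted Legendre P1, P2).
drift_basis <- function(u) {
  cbind(sqrt(12) * (u - 0.5), sqrt(180) * (u^2 - u + 1 / 6))
}

#' Synthesize one vowel trial
#'
#' Generates an impulse-train source at the target's f0 and filters it
#' through a cascade of four second-order resonators whose center
#' frequencies are the target formants shifted by `trial_offset_mel` (per
#' formant, on the Mel scale) plus a smooth within-trial drift. The drift is
#' a zero-mean quadratic with random coefficients scaled so the expected
#' within-trial Mel SD equals `within_drift$sd_mel`; it is applied to F1 and
#' F2 (the formants entering the variability metrics). The source is ramped
#' on/off over 10 ms and the result peak-normalized to -6 dBFS before the
#' `intensity_db` shift.
#'
#' @param target A vowel target (see [vowel_targets()]).
#' @param trial_offset_mel Length-4 Mel offset added per formant.
#' @param within_drift List with `sd_mel` and optionally `coef`, a 2x2 matrix
#'   of standard-normal drift coefficients (rows: F1, F2); drawn from `seed`
#'   when absent.
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed for any randomness not pinned by `coef`.
#' @param duration Vowel duration in s (default the target's base duration).
#' @param intensity_db Intensity shift in dB relative to -6 dBFS peak.
#' @param onset Lead-in silence before vowel onset, in s.
#' @return A synthetic trial: list with `waveform` (`samples`, `fs`),
#'   `truth_track` (frame times at 5-ms hop and exact F/B values used),
#'   `onset`, `offset` and `meta`.
#' @export
synthesize_vowel <- function(target, trial_offset_mel = c(0, 0, 0, 0),
                             within_drift = list(sd_mel = 0), fs = 44100,
                             seed = NULL, duration = NULL, intensity_db = 0,
                             onset = 0.06) {
  validate_vowel_target(target)
  stopifnot(all(is.finite(trial_offset_mel)), length(trial_offset_mel) == 4)
  if (is.null(duration)) duration <- target$base_duration
  if (duration < 0.1) stop("synthesize_vowel: vowel duration must be >= 0.1 s")

  sd_mel <- within_drift$sd_mel %||% 0
  coef <- within_drift$coef
  if (is.null(coef)) {
    if (sd_mel > 0) {
      if (!is.null(seed)) {
        coef <- local_seed(seed, matrix(stats::rnorm(4), 2, 2))
      } else {
        coef <- matrix(stats::rnorm(4), 2, 2)
      }
    } else {
      coef <- matrix(0, 2, 2)
    }
  }

  hop <- 0.005
  offset_t <- onset + duration
  n_frames <- floor(duration / hop)
  frame_times <- onset + (seq_len(n_frames) - 0.5) * hop
  u <- (frame_times - onset) / duration

  # Per-frame formant frequencies in Hz: Mel shift + Mel drift (F1, F2 only)
  base_mel <- hz_to_mel(target$F) + trial_offset_mel
  drift <- drift_basis(u) # n_frames x 2
  F_hz <- matrix(0, n_frames, 4, dimnames = list(NULL, paste0("F", 1:4)))
  for (k in 1:4) {
    mel_k <- base_mel[k]
    if (k <= 2 && sd_mel > 0) {
      mel_k <- mel_k + (sd_mel / sqrt(2)) * drop(drift %*% coef[k, ])
    }
    if (any(mel_k <= 0)) stop("synthesize_vowel: offset pushes formant ", k, " below 0 Hz")
    F_hz[, k] <- mel_to_hz(mel_k)
  }
  if (any(F_hz >= fs / 2)) {
    stop("synthesize_vowel: formant frequency at or above Nyquist")
  }
  if (any(diff(t(F_hz)) <= 0)) {
    stop("synthesize_vowel: formant ordering violated after offsets")
  }

  tail_s <- 0.05
  n_total <- round((onset + duration + tail_s) * fs)
  src <- numeric(n_total)
  period <- fs / target$f0
  pulse_idx <- round(onset * fs + seq(0, duration * fs - 1, by = period)) + 1L
  pulse_idx <- pulse_idx[pulse_idx <= n_total]
  src[pulse_idx] <- 1

  # 10-ms raised-cosine on/off ramps applied to the source
  ramp_n <- round(0.010 * fs)
  t_rel <- (pulse_idx - 1) / fs - onset
  gain <- rep(1, length(pulse_idx))
  rise <- t_rel < ramp_n / fs
  gain[rise] <- 0.5 * (1 - cos(pi * t_rel[rise] * fs / ramp_n))
  fall <- t_rel > duration - ramp_n / fs
  gain[fall] <- 0.5 * (1 - cos(pi * (duration - t_rel[fall]) * fs / ramp_n))
  src[pulse_idx] <- src[pulse_idx] * pmax(0, gain)

  # Blockwise cascade filtering: coefficients constant within each 5-ms frame
  y <- src
  block_bounds <- round(c(onset * fs, onset * fs + seq_len(n_frames) * hop * fs))
  block_bounds[length(block_bounds)] <- n_total # let ringing decay in the tail
  for (k in 1:4) {
    r <- exp(-pi * target$B[k] / fs)
    out <- y
    state <- c(0, 0) # y[n-1], y[n-2]
    for (b in seq_len(n_frames)) {
      i0 <- block_bounds[b] + 1L
      i1 <- block_bounds[b + 1L]
      if (i1 < i0) next
      theta <- 2 * pi * F_hz[b, k] / fs
      cb <- 2 * r * cos(theta)
      cc <- -r * r
      a <- 1 - cb - cc # unit gain at DC
      seg <- stats::filter(a * y[i0:i1], c(cb, cc), method = "recursive",
                           init = state)
      out[i0:i1] <- seg
      state <- c(seg[length(seg)], if (length(seg) >= 2) seg[length(seg) - 1] else state[1])
    }
    out[seq_len(block_bounds[1])] <- 0
    y <- out
  }

  peak <- max(abs(y))
  if (peak == 0) stop("synthesize_vowel: degenerate all-zero synthesis")
  y <- y / peak * 0.5 * 10^(intensity_db / 20) # -6 dBFS before shift
  y <- pmin(1, pmax(-1, y))

  list(
    waveform = list(samples = y, fs = fs),
    truth_track = list(frame_times = frame_times, F = F_hz,
                       B = matrix(target$B, n_frames, 4, byrow = TRUE,
                                  dimnames = list(NULL, paste0("B", 1:4)))),
    onset = onset, offset = offset_t,
    meta = list(vowel = target$label)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw the per-trial parameter plan for a cohort
#'
#' Draws every random quantity in the design up front: per-trial Mel formant
#' offsets (SD `sigma_trial[group, condition]` times the vowel scale),
#' within-trial drift coefficients, duration and intensity jitter, and
#' lead-in onset jitter. DAF trials get their duration multiplied by
#' `daf_duration_factor` and intensity shifted by `daf_intensity_shift`.
#' Synthesizing trial `i` of the plan is then fully deterministic, which
#' allows cohorts to be generated streamingly and reproducibly.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per trial: identifiers, realized
#'   duration/intensity/onset, per-formant Mel offsets `off1..off4` and
#'   drift coefficients `z11, z12, z21, z22`.
#' @export
cohort_trial_plan <- function(config) {
  validate_cohort_config(config)
  groups <- c("AWS", "ANS")
  conditions <- c("NAF", "DAF")
  vowels <- names(config$vowel_targets)
  n_tr <- config$trials_per_vowel_per_condition

  grid <- expand.grid(
    trial = seq_len(n_tr), vowel = vowels, condition = conditions,
    subj = seq_len(config$n_per_group), group = groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  local_seed(config$seed, {
    off <- matrix(stats::rnorm(4 * n), n, 4)
    zz <- matrix(stats::rnorm(4 * n), n, 4)
    dur_j <- exp(stats::rnorm(n, 0, config$duration_jitter_sd))
    int_j <- stats::rnorm(n, 0, config$intensity_jitter_sd)
    onset_j <- stats::runif(n, 0, 0.02)
  })

  sigma <- config$sigma_trial[cbind(grid$group, grid$condition)] *
    config$vowel_sigma_scale[grid$vowel]
  off <- off * sigma # recycles per column: offsets share the trial's SD

  base_dur <- vapply(config$vowel_targets, function(t) t$base_duration, 0)
  base_int <- vapply(config$vowel_targets, function(t) t$base_intensity, 0)
  is_daf <- grid$condition == "DAF"
  duration <- base_dur[grid$vowel] * dur_j *
    ifelse(is_daf, config$daf_duration_factor, 1)
  intensity <- base_int[grid$vowel] + int_j +
    ifelse(is_daf, config$daf_intensity_shift, 0)

  participant <- sprintf("%s%02d", grid$group, grid$subj)
  data.frame(
    trial_id = sprintf("%s_%s_%s_%02d", participant, grid$condition,
                       grid$vowel, grid$trial),
    participant = participant, group = grid$group, condition = grid$condition,
    vowel = grid$vowel, trial = grid$trial,
    duration = duration, intensity_db = intensity, onset = 0.06 + onset_j,
    off1 = off[, 1], off2 = off[, 2], off3 = off[, 3], off4 = off[, 4],
    z11 = zz[, 1], z12 = zz[, 2], z21 = zz[, 3], z22 = zz[, 4],
    sigma_within = config$sigma_within * config$vowel_within_scale[grid$vowel],
    stringsAsFactors = FALSE
  )
}

#' Synthesize one trial of a cohort plan
#'
#' @param plan_row One row of [cohort_trial_plan()].
#' @param config The same [cohort_config()] used to build the plan.
#' @return A synthetic trial (see [synthesize_vowel()]) with full metadata.
#' @export
synthesize_trial <- function(plan_row, config) {
  target <- config$vowel_targets[[plan_row$vowel]]
  tr <- synthesize_vowel(
    target,
    trial_offset_mel = as.numeric(plan_row[c("off1", "off2", "off3", "off4")]),
    within_drift = list(
      sd_mel = plan_row$sigma_within,
      coef = matrix(as.numeric(plan_row[c("z11", "z12", "z21", "z22")]),
                    2, 2, byrow = TRUE)
    ),
    fs = config$fs, duration = plan_row$duration,
    intensity_db = plan_row$intensity_db, onset = plan_row$onset
  )
  tr$meta <- list(
    trial_id = plan_row$trial_id, participant = plan_row$participant,
    group = plan_row$group, condition = plan_row$condition,
    vowel = plan_row$vowel, trial = plan_row$trial
  )
  tr
}

#' Simulate a full synthetic cohort
#'
#' Draws the trial plan and synthesizes every trial. For the default design
#' this is 2 groups x 12 participants x 2 conditions x 4 vowels x 24 trials
#' = 4,608 trials; use [cohort_trial_plan()] + [synthesize_trial()] to
#' stream instead of holding all audio in memory.
#'
#' @param config A [cohort_config()].
#' @return List with `trials` (list of synthetic trials) and `annotations`
#'   (data frame: trial_id, participant, group, condition, vowel, wav_path,
#'   onset_s, offset_s, excluded).
#' @export
simulate_cohort <- function(config) {
  plan <- cohort_trial_plan(config)
  trials <- lapply(seq_len(nrow(plan)), function(i) {
    synthesize_trial(plan[i, ], config)
  })
  list(trials = trials, annotations = annotations_from_trials(trials))
}

annotations_from_trials <- function(trials) {
  data.frame(
    trial_id = vapply(trials, function(t) t$meta$trial_id %||% NA_character_, ""),
    participant = vapply(trials, function(t) t$meta$participant %||% NA_character_, ""),
    group = vapply(trials, function(t) t$meta$group %||% NA_character_, ""),
    condition = vapply(trials, function(t) t$meta$condition %||% NA_character_, ""),
    vowel = vapply(trials, function(t) t$meta$vowel %||% NA_character_, ""),
    wav_path = vapply(trials, function(t) paste0(t$meta$trial_id %||% "trial", ".wav"), ""),
    onset_s = vapply(trials, function(t) t$onset, 0),
    offset_s = vapply(trials, function(t) t$offset, 0),
    excluded = rep(0L, length(trials)),
    stringsAsFactors = FALSE
  )
}

#' Write a set of synthetic trials to disk
#'
#' One mono PCM16 WAV per trial plus an `annotations.csv` with one row per
#' trial (columns: trial_id, participant, group, condition, vowel, wav_path,
#' onset_s, offset_s, excluded).
#'
#' @param trials List of synthetic trials (possibly empty).
#' @param directory Output directory (created if missing).
#' @return The annotation data frame, invisibly.
#' @export
write_dataset <- function(trials, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ann <- annotations_from_trials(if (length(trials)) trials else list())
  if (length(trials) == 0) {
    ann <- ann[0, , drop = FALSE]
  }
  for (t in trials) {
    write_wav(t$waveform$samples, t$waveform$fs,
              file.path(directory, paste0(t$meta$trial_id %||% "trial", ".wav")))
  }
  utils::write.csv(ann, file.path(directory, "annotations.csv"),
                   row.names = FALSE)
  invisible(ann)
}

#' Read a dataset annotation table
#'
#' @param path Path to an `annotations.csv` written by [write_dataset()].
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "participant", "group", "condition", "vowel",
                "wav_path", "onset_s", "offset_s", "excluded")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop("read_annotations: missing columns: ", paste(missing, collapse = ", "))
  }
  ann
}
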