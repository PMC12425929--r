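# Shared fixtures: tiny cohort configurations and synthetic tracks built in
# code so no binary data ships with the package.

tiny_cohort <- function(n_per_group = 1, trials = 2, seed = 11, ...) {
  cohort_config(n_per_group = n_per_group,
                trials_per_vowel_per_condition = trials, seed = seed, ...)
}

# A deterministic formant track with constant formants, 5-ms hop.
flat_track <- function(f = c(500, 1500, 2500, 3500), n_frames = 60,
                       hop = 0.005, t0 = 0) {
  list(
    frame_times = t0 + (seq_len(n_frames) - 0.5) * hop,
    F = matrix(f, n_frames, 4, byrow = TRUE,
               dimnames = list(NULL, paste0("F", 1:4))),
    B = matrix(c(80, 120, 160, 200), n_frames, 4, byrow = TRUE),
    flagged = rep(FALSE, n_frames),
    candidates = NULL
  )
}

# Trial-measure rows for a full balanced design, generated from the
# cell-level model (no audio), for metrics/stats tests.
fake_measures <- function(n_per_group = 12, trials = 24, sd_m = 10,
                          sd_s = 2, seed = 5) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      trial = seq_len(trials), vowel = c("i", "ih", "eh", "ae"),
      condition = c("NAF", "DAF"), subj = seq_len(n_per_group),
      group = c("AWS", "ANS"), KEEP.OUT.ATTRS = FALSE,
      stringsAsFactors = FALSE
    )
    n <- nrow(grid)
    base1 <- c(i = 430, ih = 520, eh = 620, ae = 700)
    base2 <- c(i = 1800, ih = 1700, eh = 1600, ae = 1550)
    data.frame(
      participant = sprintf("%s%02d", grid$group, grid$subj),
      group = grid$group, condition = grid$condition, vowel = grid$vowel,
      m1 = base1[grid$vowel] + rnorm(n, 0, sd_m),
      m2 = base2[grid$vowel] + rnorm(n, 0, sd_m),
      s1 = abs(rnorm(n, 5, sd_s)) + 0.5,
      s2 = abs(rnorm(n, 5, sd_s)) + 0.5,
      duration_ms = 250 + rnorm(n, 0, 10),
      intensity_db = -20 + rnorm(n, 0, 1),
      stringsAsFactors = FALSE
    )
  })
}
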