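test_that("TTV matches hand calculations and basic properties", {
  same <- data.frame(m1 = rep(500, 5), m2 = rep(1500, 5))
  expect_equal(trial_to_trial_variability(same), 0)

  two <- data.frame(m1 = c(0, 2), m2 = c(0, 0))
  expect_equal(trial_to_trial_variability(two), 1)

  expect_error(trial_to_trial_variability(data.frame(m1 = 1, m2 = 2)),
               "at least 2")

  withr::with_seed(2, {
    tr <- data.frame(m1 = rnorm(24, 500, 8), m2 = rnorm(24, 1500, 8))
    base <- trial_to_trial_variability(tr)
    # translation invariance
    shifted <- data.frame(m1 = tr$m1 + 100, m2 = tr$m2 - 50)
    expect_equal(trial_to_trial_variability(shifted), base)
    # scale equivariance of deviations
    scaled <- data.frame(m1 = mean(tr$m1) + 3 * (tr$m1 - mean(tr$m1)),
                         m2 = mean(tr$m2) + 3 * (tr$m2 - mean(tr$m2)))
    expect_equal(trial_to_trial_variability(scaled), 3 * base)
  })

  # median centering is available and differs in general
  skewed <- data.frame(m1 = c(0, 0, 30), m2 = c(0, 0, 0))
  expect_false(trial_to_trial_variability(skewed, center = "median") ==
                 trial_to_trial_variability(skewed, center = "mean"))
})

test_that("mean TTV over many cells matches the analytic expectation", {
  sigma <- 10; n <- 24
  withr::with_seed(3, {
    ttv <- replicate(1000, trial_to_trial_variability(
      data.frame(m1 = rnorm(n, 500, sigma), m2 = rnorm(n, 1500, sigma))))
  })
  expected <- sigma * sqrt(2) * sqrt((n - 1) / n)
  expect_lt(abs(mean(ttv) - expected) / expected, 0.02)
})

test_that("WTV matches its hand calculation and ignores between-trial spread", {
  expect_equal(within_trial_variability(data.frame(s1 = 3, s2 = 4)),
               sqrt((9 + 16) / 2))
  zero <- data.frame(s1 = rep(0, 6), s2 = rep(0, 6))
  expect_equal(within_trial_variability(zero), 0)

  withr::with_seed(4, {
    tr <- data.frame(m1 = rnorm(10, 500, 20), m2 = rnorm(10, 1500, 20),
                     s1 = abs(rnorm(10, 5, 1)), s2 = abs(rnorm(10, 5, 1)))
    base <- within_trial_variability(tr)
    perm <- tr
    perm$m1 <- sample(tr$m1); perm$m2 <- sample(tr$m2) # permute trial means
    expect_equal(within_trial_variability(perm), base)
  })
})

test_that("inter-vowel distance matches geometry and is translation invariant", {
  sq <- data.frame(vowel = c("i", "ih", "eh", "ae"),
                   c1 = c(0, 1, 0, 1), c2 = c(0, 0, 1, 1))
  expect_equal(inter_vowel_distance(sq), (4 + 2 * sqrt(2)) / 6)
  expect_equal(inter_vowel_distance(transform(sq, c1 = c1 + 10, c2 = c2 - 3)),
               (4 + 2 * sqrt(2)) / 6)
  same <- transform(sq, c1 = 5, c2 = 7)
  expect_equal(inter_vowel_distance(same), 0)
  expect_error(inter_vowel_distance(sq[1:3, ]), "missing vowels: ae")
})

test_that("the analysis table has one log-transformed row per cell", {
  meas <- fake_measures(n_per_group = 12, trials = 24)
  tab <- build_analysis_table(meas)
  expect_equal(nrow(tab), 24 * 4 * 2) # 192 cells
  expect_true(all(tab$n_trials == 24))
  expect_equal(exp(tab$log_ttv), tab$ttv_mel, tolerance = 1e-12)
  expect_equal(exp(tab$log_wtv), tab$wtv_mel, tolerance = 1e-12)

  # doubling every formant deviation shifts log TTV by exactly log(2)
  key <- interaction(meas$participant, meas$vowel, meas$condition)
  doubled <- meas
  for (cell in split(seq_len(nrow(meas)), key)) {
    doubled$m1[cell] <- mean(meas$m1[cell]) + 2 * (meas$m1[cell] - mean(meas$m1[cell]))
    doubled$m2[cell] <- mean(meas$m2[cell]) + 2 * (meas$m2[cell] - mean(meas$m2[cell]))
  }
  tab2 <- build_analysis_table(doubled)
  ord <- function(t) t[order(t$participant, t$vowel, t$condition), ]
  expect_equal(ord(tab2)$log_ttv, ord(tab)$log_ttv + log(2), tolerance = 1e-12)

  expect_error(build_analysis_table(meas[0, ]), "empty")

  # zero-variability cells are dropped with a warning
  const <- meas[meas$participant == "AWS01" & meas$vowel == "i" &
                  meas$condition == "NAF", ]
  const$m1 <- 500; const$m2 <- 1500; const$s1 <- 0; const$s2 <- 0
  rest <- meas[!(meas$participant == "AWS01" & meas$vowel == "i" &
                   meas$condition == "NAF"), ]
  expect_warning(tab3 <- build_analysis_table(rbind(rest, const)),
                 "zero variability")
  expect_equal(nrow(tab3), 191)
})

test_that("TTV from tracked audio agrees with TTV from ground truth", {
  # >= 100 cells spanning a wide dispersion range; r > 0.95 required
  tgs <- vowel_targets()
  cfg <- tracker_config()
  n_cells <- 100; n_trials <- 8
  withr::with_seed(12, {
    sigmas <- runif(n_cells, 4, 30)
    ttv <- t(vapply(seq_len(n_cells), function(ci) {
      tg <- tgs[[(ci - 1) %% 4 + 1]]
      m_tr <- matrix(0, n_trials, 2); m_th <- matrix(0, n_trials, 2)
      for (j in seq_len(n_trials)) {
        off <- c(rnorm(2, 0, sigmas[ci]), 0, 0)
        tr <- synthesize_vowel(tg, trial_offset_mel = off,
                               within_drift = list(sd_mel = 6), seed = ci * 100 + j)
        span <- vowel_span(tr$onset, tr$offset)
        win <- extract_window(track_formants(tr$waveform, cfg), span)
        m_tr[j, ] <- c(mean(hz_to_mel(win$F[, 1])), mean(hz_to_mel(win$F[, 2])))
        tw <- extract_window(
          list(frame_times = tr$truth_track$frame_times, F = tr$truth_track$F,
               B = tr$truth_track$B,
               flagged = rep(FALSE, nrow(tr$truth_track$F)), candidates = NULL),
          span)
        m_th[j, ] <- c(mean(hz_to_mel(tw$F[, 1])), mean(hz_to_mel(tw$F[, 2])))
      }
      c(trial_to_trial_variability(data.frame(m1 = m_tr[, 1], m2 = m_tr[, 2])),
        trial_to_trial_variability(data.frame(m1 = m_th[, 1], m2 = m_th[, 2])))
    }, c(0, 0)))
  })
  expect_gt(cor(ttv[, 1], ttv[, 2]), 0.95)
})
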