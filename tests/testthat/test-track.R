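test_that("Mel conversion matches its closed form and inverts exactly", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  for (x in c(100, 1000, 4000)) {
    expect_lt(abs(mel_to_hz(hz_to_mel(x)) - x), 1e-9)
  }
  expect_error(hz_to_mel(-1), "non-negative")
  # strictly increasing and concave on a grid
  grid <- seq(0, 8000, by = 10)
  m <- hz_to_mel(grid)
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(diff(m)) <= 0))
})

test_that("pre-emphasis has its closed-form responses", {
  w <- list(samples = rep(2, 10), fs = 100)
  expect_identical(preemphasize(w, 0)$samples, w$samples)
  out <- preemphasize(w, 0.97)$samples
  expect_equal(out[1], 2)
  expect_equal(out[-1], rep(0.03 * 2, 9))
  imp <- list(samples = c(rep(0, 5), 1, rep(0, 4)), fs = 100)
  out <- preemphasize(imp, 0.97)$samples
  expect_equal(out[6], 1)
  expect_equal(out[7], -0.97)
  expect_true(all(out[-c(6, 7)] == 0))
})

test_that("LPC solves the least-squares problem and recovers AR processes", {
  withr::with_seed(8, {
    # prediction never increases error variance
    frame <- rnorm(512)
    fit <- lpc_coefficients(frame, 2)
    expect_lte(fit$gain, sum(frame^2))

    # AR(2) coefficient recovery at frame length 2048
    a_true <- c(0.75, -0.5)
    x <- as.numeric(stats::arima.sim(list(ar = a_true), 2048))
    fit <- lpc_coefficients(x, 2)
    expect_lt(max(abs(fit$a - a_true)), 0.05)
  })
  expect_error(lpc_coefficients(rep(0, 100), 10), "degenerate")
})

test_that("Levinson-Durbin equals the direct Toeplitz solve", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      order <- sample(4:16, 1)
      n <- 256
      frame <- rnorm(n) + 0.8 * sin(2 * pi * (1:n) / 17)
      r <- vapply(0:order, function(k) sum(frame[1:(n - k)] * frame[(1 + k):n]), 0)
      direct <- solve(stats::toeplitz(r[1:order]), r[2:(order + 1)])
      fit <- lpc_coefficients(frame, order)
      expect_lt(max(abs(fit$a - direct)), 1e-8)
    }
  })
})

test_that("pole angles and moduli map to frequencies and bandwidths", {
  # conjugate pole pair at angle pi/2, modulus 0.99:
  # A(z) = 1 - 2 m cos(theta) z^-1 + m^2 z^-2
  m <- 0.99; theta <- pi / 2; fs <- 8000
  a <- c(2 * m * cos(theta), -m^2)
  cand <- roots_to_candidates(a, fs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$frequency, 2000, tolerance = 1e-9)
  expect_equal(cand$bandwidth, -(8000 / pi) * log(0.99), tolerance = 1e-9)

  # real-only poles yield no candidates: (1 - .5 z^-1)(1 - .3 z^-1)
  cand <- roots_to_candidates(c(0.8, -0.15), fs)
  expect_equal(nrow(cand), 0)
})

test_that("tracker recovers steady and ramping formants", {
  tg <- vowel_targets()$eh
  tr <- synthesize_vowel(tg)
  trk <- track_formants(tr$waveform, tracker_config())
  win <- extract_window(trk, vowel_span(tr$onset, tr$offset))
  expect_lt(abs(mean(win$F[, 1]) - tg$F[1]), 30)
  expect_lt(abs(mean(win$F[, 2]) - tg$F[2]), 50)
  # ordering invariant on every emitted frame
  expect_true(all(apply(trk$F, 1, function(f) all(diff(f) > 0))))

  # linear-in-Mel F1 ramp covering 400 -> 500 Hz: pin the drift to its
  # first (linear) basis function
  ramp <- tg
  ramp$F[1] <- mel_to_hz((hz_to_mel(400) + hz_to_mel(500)) / 2)
  half_range_mel <- (hz_to_mel(500) - hz_to_mel(400)) / 2
  sd_mel <- half_range_mel * sqrt(2) / (sqrt(12) * 0.5)
  tr <- synthesize_vowel(ramp, within_drift = list(
    sd_mel = sd_mel, coef = matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)))
  expect_equal(range(tr$truth_track$F[, 1]), c(400, 500), tolerance = 0.02)
  trk <- track_formants(tr$waveform, tracker_config())
  inner <- trk$frame_times > tr$onset + 0.02 &
    trk$frame_times < tr$offset - 0.02
  truth_f1 <- approx(tr$truth_track$frame_times, tr$truth_track$F[, 1],
                     xout = trk$frame_times[inner], rule = 2)$y
  expect_true(all(abs(trk$F[inner, 1] - truth_f1) < 30))
  expect_true(all(diff(trk$F[inner, 1]) > -30)) # monotone up to tolerance
})

test_that("median tracking error is small across randomized vowels", {
  tgs <- vowel_targets()
  cfg <- tracker_config()
  withr::with_seed(42, {
    errs <- t(vapply(1:100, function(i) {
      tg <- tgs[[(i - 1) %% 4 + 1]]
      tg$F[1:2] <- tg$F[1:2] + runif(2, -30, 30)
      tr <- synthesize_vowel(tg)
      win <- extract_window(track_formants(tr$waveform, cfg),
                            vowel_span(tr$onset, tr$offset))
      colMeans(win$F[, 1:2]) - tg$F[1:2]
    }, c(0, 0)))
  })
  expect_lte(median(abs(errs[, 1])), 15)
  expect_lte(median(abs(errs[, 2])), 30)
})

test_that("degenerate input is flagged or refused", {
  silence <- list(samples = rep(0, 44100 / 2), fs = 44100)
  trk <- track_formants(silence, tracker_config())
  expect_true(all(trk$flagged))
  expect_error(track_formants(list(samples = rep(0.1, 50), fs = 44100)),
               "shorter than one frame")
})

test_that("formant tracks round-trip through CSV", {
  tg <- vowel_targets()$i
  tr <- synthesize_vowel(tg)
  trk <- track_formants(tr$waveform, tracker_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(trk, path)
  back <- read_track_csv(path)
  expect_equal(back$frame_times, trk$frame_times)
  expect_equal(unname(back$F), unname(trk$F))
  expect_equal(back$flagged, trk$flagged)
})
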