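# LPC formant tracking.
#
# The tracker follows the classical offline design: decimate to an internal
# rate that puts the four vowel formants below Nyquist, pre-emphasize, window
# into overlapping frames, fit an all-pole model per frame by the
# autocorrelation method (Levinson-Durbin), convert pole angles/moduli to
# formant frequency/bandwidth candidates, and assign candidates to formant
# slots by dynamic programming that trades off closeness to nominal formant
# positions, candidate bandwidth, and inter-frame continuity.

#' Formant tracker configuration
#'
#' @param lpc_order All-pole model order. 17 is the usual choice for adult
#'   male speech (15 for female) at the ~11 kHz internal rate.
#' @param preemphasis First-order pre-emphasis coefficient in \[0, 1). The
#'   default 0.8 is milder than the ~0.97 typical for real speech: pre-
#'   emphasis exists to undo the falling glottal source spectrum, and the
#'   synthetic impulse-train source is spectrally flat, so heavy
#'   pre-emphasis over-whitens and biases low F1 estimates upward. For real
#'   recordings raise it towards 0.97.
#' @param frame_length Analysis frame length in s.
#' @param frame_hop Frame hop in s (5 ms puts ~10 frames in a 50-ms window).
#' @param window Taper: `"hamming"`, `"hann"` or `"rectangular"`.
#' @param n_formants_out Number of formant slots to emit.
#' @param dp_weights Named weights `continuity`, `bandwidth`, `nominal` for
#'   the dynamic-programming cost. Continuity and nominal terms act on
#'   squared natural-log frequency differences, the bandwidth term on B/F,
#'   so the defaults put the three terms on comparable scales.
#' @param nominal_formants Nominal slot frequencies in Hz.
#' @param internal_fs Internal analysis rate in Hz; input audio at a higher
#'   rate is decimated (with anti-aliasing) by an integer factor first.
#' @return Tracker configuration list.
#' @export
tracker_config <- function(lpc_order = 17, preemphasis = 0.8,
                           frame_length = 0.025, frame_hop = 0.005,
                           window = "hamming", n_formants_out = 4,
                           dp_weights = c(continuity = 1, bandwidth = 1,
                                          nominal = 0.25),
                           nominal_formants = c(500, 1500, 2500, 3500),
                           internal_fs = 11025) {
  cfg <- list(lpc_order = as.integer(lpc_order), preemphasis = preemphasis,
              frame_length = frame_length, frame_hop = frame_hop,
              window = window, n_formants_out = as.integer(n_formants_out),
              dp_weights = dp_weights, nominal_formants = nominal_formants,
              internal_fs = internal_fs)
  stopifnot(
    cfg$lpc_order >= 2 * cfg$n_formants_out,
    cfg$preemphasis >= 0, cfg$preemphasis < 1,
    cfg$frame_hop > 0, cfg$frame_hop <= cfg$frame_length,
    all(c("continuity", "bandwidth", "nominal") %in% names(cfg$dp_weights)),
    length(cfg$nominal_formants) >= cfg$n_formants_out
  )
  cfg
}

#' First-order pre-emphasis filter
#'
#' `output[n] = input[n] - a * input[n-1]`, with `output[1] = input[1]`.
#' Flattens the falling glottal source spectrum before LPC fitting.
#'
#' @param w Waveform (`list(samples, fs)`).
#' @param a Coefficient in \[0, 1).
#' @return Pre-emphasized waveform.
#' @export
preemphasize <- function(w, a) {
  stopifnot(a >= 0, a < 1)
  x <- w$samples
  w$samples <- x - a * c(0, x[-length(x)])
  w
}

#' Linear-prediction coefficients by the autocorrelation method
#'
#' Solves the Toeplitz normal equations with the Levinson-Durbin recursion.
#' The returned `a` are prediction coefficients: `x[n] ~ sum(a[k] x[n-k])`,
#' so the error-filter polynomial is `c(1, -a)` and the autocorrelation
#' method guarantees a minimum-phase result (all poles inside the unit
#' circle).
#'
#' @param frame Windowed sample block (numeric, length > order).
#' @param order Model order.
#' @return List with `a` (length `order`) and `gain` (residual power).
#' @export
lpc_coefficients <- function(frame, order) {
  n <- length(frame)
  stopifnot(n > order, order >= 1)
  if (all(frame == 0)) stop("lpc_coefficients: degenerate all-zero frame")
  r <- vapply(0:order, function(k) {
    sum(frame[1:(n - k)] * frame[(1 + k):n])
  }, 0)
  if (r[1] <= 0) stop("lpc_coefficients: degenerate frame (zero energy)")
  # Levinson-Durbin on A(z) = 1 + alpha_1 z^-1 + ... + alpha_p z^-p
  alpha <- numeric(order)
  err <- r[1]
  for (m in seq_len(order)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc + sum(alpha[1:(m - 1)] * r[m:2])
    k <- -acc / err
    new_alpha <- alpha
    new_alpha[m] <- k
    if (m > 1) new_alpha[1:(m - 1)] <- alpha[1:(m - 1)] + k * alpha[(m - 1):1]
    alpha <- new_alpha
    err <- err * (1 - k^2)
    if (err <= 0) break
  }
  list(a = -alpha, gain = err)
}

#' Formant candidates from LPC poles
#'
#' Each complex pole `z = m exp(i theta)` with `theta` in (0, pi) yields a
#' candidate at frequency `theta * fs / (2 pi)` Hz with bandwidth
#' `-(fs / pi) * log(m)` Hz. Candidates below 50 Hz or above fs/2 - 50 Hz
#' are discarded; the rest are sorted by frequency.
#'
#' @param coefficients Output of [lpc_coefficients()] (or its `a` vector).
#' @param fs Sampling rate of the analyzed signal in Hz.
#' @return Data frame with columns `frequency` and `bandwidth` (possibly
#'   zero rows).
#' @export
roots_to_candidates <- function(coefficients, fs) {
  a <- if (is.list(coefficients)) coefficients$a else coefficients
  roots_inv <- polyroot(c(1, -a)) # roots in z^{-1}
  z <- 1 / roots_inv              # poles
  theta <- Arg(z)
  keep <- theta > 0 & theta < pi & Mod(z) > 0
  z <- z[keep]
  freq <- Arg(z) * fs / (2 * pi)
  bw <- -(fs / pi) * log(Mod(z))
  keep <- freq >= 50 & freq <= fs / 2 - 50
  out <- data.frame(frequency = freq[keep], bandwidth = bw[keep])
  out[order(out$frequency), , drop = FALSE]
}

frame_taper <- function(n, window) {
  switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    rectangular = rep(1, n),
    stop("unknown window: ", window)
  )
}

# All increasing-frequency assignments of candidates to formant slots.
# Returns index matrix (n_states x n_slots) or NULL when impossible.
slot_combinations <- function(n_cand, n_slots) {
  if (n_cand < n_slots) return(NULL)
  t(utils::combn(n_cand, n_slots))
}

#' Track formant trajectories
#'
#' Runs the full LPC analysis chain on a waveform and assigns per-frame
#' formant candidates to slots 1..`n_formants_out` by minimizing, jointly
#' across frames (Viterbi dynamic programming), the sum of squared
#' log-frequency deviations from the nominal slot frequencies, a bandwidth
#' penalty, and squared inter-frame log-frequency jumps. Frames with no
#' usable LPC fit, or with fewer candidates than slots, are filled with the
#' nominal frequencies and flagged. Exact cost ties are broken toward the
#' assignment with the lowest total bandwidth.
#'
#' @param w Waveform (`list(samples, fs)`).
#' @param cfg A [tracker_config()].
#' @return A formant track: list with `frame_times` (s, frame centers on the
#'   original time axis), `F` and `B` (frames x slots matrices, Hz),
#'   `flagged` (logical per frame) and `candidates` (per-frame candidate
#'   data frames, for diagnostics).
#' @export
track_formants <- function(w, cfg = tracker_config()) {
  stopifnot(w$fs > 0, length(w$samples) > 1)
  x <- w$samples
  fs <- w$fs
  q <- max(1L, round(fs / cfg$internal_fs))
  if (q > 1) {
    x <- signal::decimate(x, q)
    fs <- fs / q
  }
  x <- preemphasize(list(samples = x, fs = fs), cfg$preemphasis)$samples

  L <- round(cfg$frame_length * fs)
  H <- round(cfg$frame_hop * fs)
  if (length(x) < L) stop("track_formants: waveform shorter than one frame")
  starts <- seq(1, length(x) - L + 1, by = H)
  n_frames <- length(starts)
  taper <- frame_taper(L, cfg$window)
  frame_times <- (starts - 1 + L / 2) / fs

  K <- cfg$n_formants_out
  nominal <- cfg$nominal_formants[1:K]
  w_c <- cfg$dp_weights[["continuity"]]
  w_b <- cfg$dp_weights[["bandwidth"]]
  w_n <- cfg$dp_weights[["nominal"]]
  silence_rms <- 1e-6 + 1e-4 * sqrt(mean(x^2))

  cand_list <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fr <- x[starts[i]:(starts[i] + L - 1)]
    if (sqrt(mean(fr^2)) < silence_rms) next
    lpc <- tryCatch(lpc_coefficients(fr * taper, cfg$lpc_order),
                    error = function(e) NULL)
    if (is.null(lpc)) next
    cand <- roots_to_candidates(lpc, fs)
    if (nrow(cand) > 0) cand_list[[i]] <- cand
  }

  Fmat <- matrix(rep(nominal, each = n_frames), n_frames, K,
                 dimnames = list(NULL, paste0("F", 1:K)))
  Bmat <- matrix(NA_real_, n_frames, K,
                 dimnames = list(NULL, paste0("B", 1:K)))
  flagged <- rep(TRUE, n_frames)

  # Per-frame state spaces: increasing assignments of candidates to slots
  states <- vector("list", n_frames)
  log_nom <- log(nominal)
  for (i in seq_len(n_frames)) {
    cand <- cand_list[[i]]
    if (is.null(cand) || nrow(cand) < K) next
    idx <- slot_combinations(nrow(cand), K)
    lf <- matrix(log(cand$frequency)[idx], nrow(idx), K)
    bw <- matrix(cand$bandwidth[idx], nrow(idx), K)
    local <- rowSums(sweep(lf, 2, log_nom)^2) * w_n +
      rowSums(bw / exp(lf)) * w_b +
      1e-9 * rowSums(bw) # deterministic tie-break: lowest total bandwidth
    states[[i]] <- list(lf = lf, f = exp(lf), bw = bw, local = local)
  }

  usable <- which(!vapply(states, is.null, TRUE))
  if (length(usable) > 0) {
    # Viterbi over usable frames (transition cost spans flagged gaps)
    cost <- states[[usable[1]]]$local
    back <- vector("list", length(usable))
    for (j in seq_along(usable)[-1]) {
      prev <- states[[usable[j - 1]]]
      cur <- states[[usable[j]]]
      # squared log-frequency jump between every state pair, via the
      # expansion |u - v|^2 = |u|^2 + |v|^2 - 2 u.v
      cross <- prev$lf %*% t(cur$lf)
      d2 <- outer(rowSums(prev$lf^2), rowSums(cur$lf^2), "+") - 2 * cross
      total <- cost + w_c * d2 # n_prev x n_cur
      back[[j]] <- max.col(-t(total), ties.method = "first")
      cost <- total[cbind(back[[j]], seq_along(cur$local))] + cur$local
    }
    best <- which.min(cost)
    sel <- integer(length(usable))
    sel[length(usable)] <- best
    for (j in rev(seq_along(usable))[-length(usable)]) {
      sel[j - 1] <- back[[j]][sel[j]]
    }
    for (j in seq_along(usable)) {
      i <- usable[j]
      st <- states[[i]]
      Fmat[i, ] <- st$f[sel[j], ]
      Bmat[i, ] <- st$bw[sel[j], ]
      flagged[i] <- FALSE
    }
  }

  list(frame_times = frame_times, F = Fmat, B = Bmat, flagged = flagged,
       candidates = cand_list)
}

#' Write a formant track as CSV
#'
#' Columns: `frame_time_s`, `F1_hz..F4_hz`, `B1_hz..B4_hz`, `flagged`.
#' The CSV is also accepted as pipeline input in place of audio.
#'
#' @param track A formant track (see [track_formants()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  k <- ncol(track$F)
  df <- data.frame(frame_time_s = track$frame_times)
  for (j in seq_len(k)) df[[paste0("F", j, "_hz")]] <- track$F[, j]
  for (j in seq_len(k)) df[[paste0("B", j, "_hz")]] <- track$B[, j]
  df$flagged <- as.integer(track$flagged)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a formant track CSV
#'
#' @param path CSV written by [write_track_csv()].
#' @return A formant track list.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  fcols <- grep("^F[0-9]+_hz$", names(df), value = TRUE)
  bcols <- grep("^B[0-9]+_hz$", names(df), value = TRUE)
  list(
    frame_times = df$frame_time_s,
    F = as.matrix(df[fcols]),
    B = as.matrix(df[bcols]),
    flagged = if ("flagged" %in% names(df)) df$flagged > 0 else
      rep(FALSE, nrow(df)),
    candidates = NULL
  )
}
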