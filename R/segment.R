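# Vowel span handling: onset/offset determination, the 50-ms feedforward
# analysis window, and per-trial duration and intensity.
#
# The pipeline default takes vowel bounds from the annotation table (the
# counterpart of manual onset/offset selection); energy-based auto-detection
# is a fallback and is flagged as such in its output.

#' Construct a vowel span
#'
#' @param onset Vowel onset in s.
#' @param offset Vowel offset in s (> onset; spans shorter than 50 ms cannot
#'   be windowed and are rejected).
#' @param source `"annotation"` or `"auto"`.
#' @return Vowel span list.
#' @export
vowel_span <- function(onset, offset, source = "annotation") {
  if (!is.finite(onset) || !is.finite(offset) || offset <= onset) {
    stop("vowel_span: need offset > onset")
  }
  if (offset - onset < 0.05) {
    stop("vowel_span: span shorter than the 50-ms analysis window")
  }
  list(onset = onset, offset = offset, source = source)
}

#' Detect vowel bounds from signal energy
#'
#' Onset is the first time the short-time RMS exceeds `threshold` times the
#' maximum RMS and stays above it for at least `sustain` s; offset is the
#' last such time. A fallback for data without annotated bounds.
#'
#' @param w Waveform.
#' @param threshold Fraction of maximum short-time RMS (default 0.2).
#' @param rms_window RMS window length in s.
#' @param hop RMS hop in s.
#' @param sustain Minimum sustained time above threshold in s.
#' @return A vowel span with `source = "auto"`.
#' @export
detect_vowel_bounds <- function(w, threshold = 0.2, rms_window = 0.010,
                                hop = 0.0025, sustain = 0.030) {
  x <- w$samples
  fs <- w$fs
  L <- max(2L, round(rms_window * fs))
  H <- max(1L, round(hop * fs))
  if (length(x) < L) stop("detect_vowel_bounds: waveform shorter than RMS window")
  starts <- seq(1, length(x) - L + 1, by = H)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + L - 1)]^2)), 0)
  peak <- max(rms)
  if (peak <= 0) stop("detect_vowel_bounds: silent input")
  above <- rms > threshold * peak
  need <- max(1L, ceiling(sustain / hop))
  run <- rle(above)
  ends <- cumsum(run$lengths)
  ok <- which(run$values & run$lengths >= need)
  if (length(ok) == 0) stop("detect_vowel_bounds: no sustained voiced region")
  first_idx <- ends[ok[1]] - run$lengths[ok[1]] + 1L
  last_idx <- ends[ok[length(ok)]]
  onset <- (starts[first_idx] - 1 + L / 2) / fs
  offset <- (starts[last_idx] - 1 + L / 2) / fs
  if (offset - onset < 0.05) {
    stop("detect_vowel_bounds: detected span shorter than 50 ms")
  }
  vowel_span(onset, offset, source = "auto")
}

#' Extract the feedforward analysis window from a track
#'
#' Keeps the frames whose centers lie in the half-open interval
#' `[onset, onset + window_s)` — the initial portion of the vowel produced
#' before auditory feedback of the ongoing production can influence it.
#'
#' @param track A formant track.
#' @param span A vowel span.
#' @param window_s Window length in s (default 0.050).
#' @param min_frames Minimum frames required (default 3).
#' @return The windowed formant track.
#' @export
extract_window <- function(track, span, window_s = 0.050, min_frames = 3) {
  keep <- track$frame_times >= span$onset &
    track$frame_times < span$onset + window_s
  if (sum(keep) < min_frames) {
    stop("extract_window: fewer than ", min_frames, " frames in the ",
         round(window_s * 1000), "-ms window")
  }
  list(frame_times = track$frame_times[keep],
       F = track$F[keep, , drop = FALSE],
       B = track$B[keep, , drop = FALSE],
       flagged = track$flagged[keep],
       candidates = track$candidates[keep])
}

#' Vowel duration in milliseconds
#'
#' @param span A vowel span.
#' @return Duration in ms.
#' @export
vowel_duration <- function(span) {
  (span$offset - span$onset) * 1000
}

#' Vowel intensity in dBFS
#'
#' RMS level of the samples inside the span, relative to full scale:
#' `20 log10(RMS)`. Only differences between conditions are meaningful (no
#' SPL calibration is assumed).
#'
#' @param w Waveform.
#' @param span A vowel span.
#' @return Intensity in dB re full scale.
#' @export
vowel_intensity <- function(w, span) {
  i0 <- max(1L, floor(span$onset * w$fs) + 1L)
  i1 <- min(length(w$samples), ceiling(span$offset * w$fs))
  if (i1 < i0) stop("vowel_intensity: span outside waveform")
  r <- sqrt(mean(w$samples[i0:i1]^2))
  if (r <= 0) stop("vowel_intensity: silent span")
  20 * log10(r)
}
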