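#' Convert frequency in Hz to Mel
#'
#' Uses the O'Shaughnessy / HTK convention
#' \deqn{mel = 2595 \log_{10}(1 + f/700).}
#' The Mel scale is approximately linear below 1 kHz and logarithmic above,
#' so equal Mel steps approximate equal perceptual pitch steps; formant
#' dispersion statistics are computed on this scale.
#'
#' @param f Frequency in Hz (vectorized). Must be non-negative.
#' @return Frequency in Mel.
#' @seealso [mel_to_hz()]
#' @export
#' @examples
#' hz_to_mel(700) # 2595 * log10(2)
hz_to_mel <- function(f) {
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("hz_to_mel: frequencies must be finite and non-negative")
  }
  2595 * log10(1 + f / 700)
}

#' Convert frequency in Mel to Hz
#'
#' Exact inverse of [hz_to_mel()].
#'
#' @param m Frequency in Mel (vectorized). Must be non-negative.
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("mel_to_hz: Mel values must be finite and non-negative")
  }
  700 * (10^(m / 2595) - 1)
}
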