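# Minimal IIR filtering support for the sweep synthesiser. No DSP package
# ships with the target environment, so the Butterworth design (bilinear
# transform of the analog prototype) and forward-backward filtering are
# implemented here directly.

poly_from_roots <- function(r) {
  p <- 1
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Butterworth high-pass filter coefficients
#'
#' Designs a digital Butterworth high-pass filter via the bilinear transform
#' with frequency prewarping. Returns transfer-function coefficients `b`
#' (numerator) and `a` (denominator).
#'
#' @param order Filter order (default 4).
#' @param fc Cutoff frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @return List with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_highpass <- function(order = 4, fc, fs) {
  if (fc <= 0 || fc >= fs / 2) abort("`fc` must lie in (0, fs/2).")
  warped <- 2 * fs * tan(pi * fc / fs)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # analog LP prototype
  p_hp <- warped / p_lp                                    # LP -> HP transform
  # n zeros at s = 0 map to z = 1; poles via bilinear s = 2fs (z-1)/(z+1)
  z_dig <- rep(1, order)
  p_dig <- (2 * fs + p_hp) / (2 * fs - p_hp)
  gain <- Re((2 * fs)^order / prod(2 * fs - p_hp)) # K = 1, n zeros at s = 0
  b <- Re(poly_from_roots(z_dig)) * gain
  a <- Re(poly_from_roots(p_dig))
  list(b = b, a = a)
}

iir_filter <- function(x, b, a) {
  # direct-form IIR via a C-level convolution pass then recursion
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive")) / a[1]
  } else {
    v <- v / a[1]
  }
  v
}

#' Zero-phase filtering
#'
#' Applies the filter forwards and backwards (odd-reflection edge padding),
#' cancelling phase distortion; the effective magnitude response is the
#' square of the single-pass response.
#'
#' @param x Numeric signal.
#' @param b,a Transfer-function coefficients, e.g. from [butter_highpass()].
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(x, b, a) {
  n <- length(x)
  pad <- 3 * max(length(a), length(b))
  if (n <= pad) abort("Signal too short for zero-phase filtering.")
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter(xp, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[pad + seq_len(n)]
}
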