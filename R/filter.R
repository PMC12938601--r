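#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed sinc band-pass applied as a single forward pass of
#' the symmetric linear-phase kernel with group-delay compensation (not
#' forward-backward filtering). The transition bandwidth is 25% of each
#' band edge, the kernel order is chosen from the narrower transition via
#' the Hamming design rule (about 3.3 / normalized width) and rounded up
#' to even so the delay is an integer number of samples.
#'
#' @param raw A [raw_recording()].
#' @param low_hz,high_hz Passband edges in Hz; `low_hz < high_hz < fs/2`.
#' @return A filtered [raw_recording()] of identical shape.
#' @export
bandpass_fir <- function(raw, low_hz = 8, high_hz = 30) {
  fs <- raw$fs
  if (!(low_hz < high_hz)) stop("low_hz must be below high_hz")
  if (high_hz >= fs / 2) stop("high_hz must be below the Nyquist frequency")
  h <- .fir_bandpass_kernel(fs, low_hz, high_hz)
  raw$samples <- .filter_zero_phase(raw$samples, h)
  raw
}

.fir_bandpass_kernel <- function(fs, low_hz, high_hz) {
  trans_lo <- 0.25 * low_hz
  trans_hi <- min(0.25 * high_hz, 0.9 * (fs / 2 - high_hz))
  n <- ceiling(3.3 * fs / min(trans_lo, trans_hi))  # Hamming design rule
  if (n %% 2 == 1) n <- n + 1                       # even order -> integer delay
  # cutoffs at the transition midpoints
  lo <- (low_hz - trans_lo / 2) / (fs / 2)
  hi <- (high_hz + trans_hi / 2) / (fs / 2)
  as.numeric(signal::fir1(n, c(lo, hi), type = "pass",
                          window = signal::hamming(n + 1)))
}

# forward convolution with delay compensation, zero padding at the edges
# (FFT-based; equivalent to direct convolution to rounding)
.filter_zero_phase <- function(x, h) {
  d <- (length(h) - 1) / 2
  n <- ncol(x)
  nfft <- stats::nextn(n + length(h) - 1, 2)
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nfft - n))))
  out <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  t(out)[, (d + 1):(d + n), drop = FALSE]
}
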