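#' Trial-averaged Welch power spectral density
#'
#' Hamming-windowed, 50%-overlap segment-averaged periodogram, averaged
#' over trials. With the default 2-s segments the frequency resolution
#' is 0.5 Hz.
#'
#' @param activation Numeric vector (single trial) or trials x time
#'   matrix of an IC activation (or channel) time series.
#' @param fs Sampling rate in Hz.
#' @param segment_s Welch segment length in seconds.
#' @return Object of class `psd`: list with `freqs` (Hz) and `power`
#'   (linear units).
#' @export
welch_psd <- function(activation, fs, segment_s = 2) {
  if (is.null(dim(activation))) activation <- matrix(activation, 1)
  if (ncol(activation) < 2 * segment_s * fs)
    stop("input too short: need at least two ", segment_s, "-s segments")
  acc <- NULL
  for (i in seq_len(nrow(activation))) {
    w <- .welch_psd_vec(activation[i, ], fs, segment_s)
    acc <- if (is.null(acc)) w$power else acc + w$power
  }
  structure(list(freqs = w$freqs, power = acc / nrow(activation)),
            class = "psd")
}

.welch_psd_vec <- function(x, fs, segment_s = 1) {
  nper <- round(segment_s * fs)
  nover <- floor(nper / 2)
  starts <- seq(1, length(x) - nper + 1, by = nper - nover)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  u <- sum(win^2)
  nf <- floor(nper / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * win
    p <- abs(stats::fft(seg))^2 / (fs * u)
    p <- p[seq_len(nf)]
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  list(freqs = (seq_len(nf) - 1) * fs / nper, power = acc / length(starts))
}

.aperiodic_eval <- function(par, f) {
  # b - log10(k + f^chi); knee k = 0 gives the fixed (linear in log-log) form
  par["b"] - log10(par["k"] + f^par["chi"])
}

.gaussian_eval <- function(peaks, f) {
  pk <- if (is.matrix(peaks)) peaks else
    cbind(peaks$a, peaks$c, peaks$w)     # columns a, c, w
  if (!nrow(pk)) return(rep(0, length(f)))
  out <- numeric(length(f))
  for (i in seq_len(nrow(pk)))
    out <- out + pk[i, 1] * exp(-(f - pk[i, 2])^2 / (2 * pk[i, 3]^2))
  out
}

# robust aperiodic fit: plain fit, then refit on the points closest to
# (or below) the first estimate so that oscillatory peaks are ignored
.fit_aperiodic <- function(f, y, knee) {
  fit_simple <- function(f, y) {
    if (!knee) {
      co <- stats::coef(stats::lm(y ~ log10(f)))
      c(b = unname(co[1]), k = 0, chi = max(0, -unname(co[2])))
    } else {
      co <- stats::coef(stats::lm(y ~ log10(f)))
      start <- c(unname(co[1]), 1, max(0.1, -unname(co[2])))
      obj <- function(p) sum((y - (p[1] - log10(max(p[2], 0) + f^max(p[3], 0))))^2)
      p <- stats::optim(start, obj, control = list(maxit = 500))$par
      c(b = p[1], k = max(0, p[2]), chi = max(0, p[3]))
    }
  }
  ap0 <- fit_simple(f, y)
  flat <- y - .aperiodic_eval(ap0, f)
  flat[flat < 0] <- 0
  mask <- flat <= stats::quantile(flat, 0.025)
  if (sum(mask) >= 4) ap0 <- fit_simple(f[mask], y[mask])
  ap0
}

#' Parameterize a power spectrum into aperiodic and periodic parts
#'
#' Models log10 power as an aperiodic component `b - log10(k + f^chi)`
#' plus Gaussian peaks `a exp(-(f - c)^2 / (2 w^2))`. The aperiodic part
#' is fitted robustly (refit on the lower envelope), peaks are extracted
#' iteratively from the flattened spectrum by largest residual, then all
#' peak parameters are jointly refined and the aperiodic part refitted on
#' the peak-subtracted spectrum.
#'
#' @param psd A [welch_psd()] result (or list with `freqs`, `power`).
#' @param range_hz Frequency range fitted.
#' @param max_peaks Maximum number of Gaussian peaks.
#' @param min_peak_height Minimum peak amplitude in log10(power) units.
#' @param peak_width_limits Allowed Gaussian SD range in Hz.
#' @param knee If `TRUE`, fit the knee parameter `k`; by default `k = 0`
#'   (the 3-40 Hz band rarely constrains a knee).
#' @return Object of class `spectral_model`: `aperiodic` (named vector
#'   b, k, chi), `peaks` (tibble a, c, w sorted by descending a),
#'   `fit_error` (mean absolute log10 residual), `r_squared`, `range_hz`.
#' @export
fit_spectral_model <- function(psd, range_hz = c(3, 40), max_peaks = 6,
                               min_peak_height = 0.1,
                               peak_width_limits = c(0.5, 6),
                               knee = FALSE) {
  sel <- psd$freqs >= range_hz[1] & psd$freqs <= range_hz[2] & psd$freqs > 0
  f <- psd$freqs[sel]
  if (length(f) < 8) stop("fit range does not cover enough PSD bins")
  y <- log10(psd$power[sel])

  ap <- .fit_aperiodic(f, y, knee)
  flat <- y - .aperiodic_eval(ap, f)

  guesses <- list()
  work <- flat
  for (i in seq_len(max_peaks)) {
    j <- which.max(work)
    height <- work[j]
    if (height < min_peak_height) break
    cf <- f[j]
    # half-height width estimate on the working spectrum
    half <- height / 2
    lo <- j; while (lo > 1 && work[lo] > half) lo <- lo - 1
    hi <- j; while (hi < length(f) && work[hi] > half) hi <- hi + 1
    fwhm <- f[hi] - f[lo]
    w0 <- min(max(fwhm / 2.355, peak_width_limits[1]), peak_width_limits[2])
    guesses[[length(guesses) + 1]] <- c(a = height, c = cf, w = w0)
    work <- work - height * exp(-(f - cf)^2 / (2 * w0^2))
  }

  refit_peaks <- function(target, pk) {
    if (!nrow(pk)) return(pk)
    n <- nrow(pk)
    par0 <- as.numeric(t(as.matrix(pk)))
    lower <- rep(c(0, range_hz[1], peak_width_limits[1]), n)
    upper <- rep(c(Inf, range_hz[2], peak_width_limits[2]), n)
    obj <- function(p) {
      pred <- .gaussian_eval(matrix(p, ncol = 3, byrow = TRUE), f)
      sum((target - pred)^2)
    }
    o <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
    m <- matrix(o$par, ncol = 3, byrow = TRUE)
    tibble::tibble(a = m[, 1], c = m[, 2], w = m[, 3])
  }

  peaks <- if (length(guesses)) {
    tibble::as_tibble(do.call(rbind, guesses))
  } else tibble::tibble(a = numeric(), c = numeric(), w = numeric())
  peaks <- refit_peaks(flat, peaks)

  # refit the aperiodic part on the peak-subtracted spectrum, then peaks
  if (nrow(peaks)) {
    ap <- .fit_aperiodic(f, y - .gaussian_eval(peaks, f), knee = knee)
    peaks <- refit_peaks(y - .aperiodic_eval(ap, f), peaks)
    keep <- peaks$a >= min_peak_height &
      peaks$c > range_hz[1] & peaks$c < range_hz[2]
    peaks <- peaks[keep, ]
    peaks <- peaks[order(-peaks$a, peaks$c), ]
  }

  resid <- y - .aperiodic_eval(ap, f) - .gaussian_eval(peaks, f)
  structure(list(aperiodic = ap, peaks = peaks,
                 fit_error = mean(abs(resid)),
                 r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2),
                 range_hz = range_hz),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<spectral_model> b=%.2f k=%.2f chi=%.2f, %d peak(s), MAE %.3f\n",
              x$aperiodic["b"], x$aperiodic["k"], x$aperiodic["chi"],
              nrow(x$peaks), x$fit_error))
  invisible(x)
}

#' Dominant oscillatory peak within a band
#'
#' Selects the largest-amplitude fitted peak whose center frequency lies
#' in `band`. The peak's amplitude in log10(power) above the aperiodic
#' fit is the component's relative power; its reported width is the
#' two-sided Gaussian SD (`2 w`). Amplitude ties go to the lower center
#' frequency (mu preferred over beta).
#'
#' @param model A [fit_spectral_model()] result.
#' @param band Frequency band in Hz, default the mu/beta band `c(8, 30)`.
#' @return Object of class `dominant_peak`: `present`, `relative_power`,
#'   `center_frequency`, `frequency_width`.
#' @export
dominant_peak <- function(model, band = c(8, 30)) {
  pk <- model$peaks
  pk <- pk[pk$c >= band[1] & pk$c <= band[2], ]
  if (!nrow(pk)) {
    return(structure(list(present = FALSE, relative_power = NA_real_,
                          center_frequency = NA_real_,
                          frequency_width = NA_real_),
                     class = "dominant_peak"))
  }
  pk <- pk[order(-pk$a, pk$c), ]
  structure(list(present = TRUE, relative_power = pk$a[1],
                 center_frequency = pk$c[1], frequency_width = 2 * pk$w[1]),
            class = "dominant_peak")
}

#' @export
print.dominant_peak <- function(x, ...) {
  if (x$present)
    cat(sprintf("<dominant_peak> a=%.2f at %.1f Hz, width %.1f Hz\n",
                x$relative_power, x$center_frequency, x$frequency_width))
  else cat("<dominant_peak> none in band\n")
  invisible(x)
}
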