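test_that("Welch PSD localizes tones and is flat for white noise", {
  fs <- 160
  t <- seq(0, 30 - 1 / fs, 1 / fs)
  p1 <- welch_psd(sin(2 * pi * 11 * t), fs)
  expect_lt(abs(p1$freqs[which.max(p1$power)] - 11), 0.25)
  p2 <- welch_psd(sin(2 * pi * 11 * t) + 0.5 * sin(2 * pi * 22 * t), fs)
  band <- function(f0) which(abs(p2$freqs - f0) < 1)
  expect_true(max(p2$power[band(11)]) > 10 * stats::median(p2$power))
  expect_true(max(p2$power[band(22)]) > 10 * stats::median(p2$power))
  set.seed(1)
  pw <- welch_psd(matrix(rnorm(40 * 30 * fs), 40), fs)
  sel <- pw$freqs >= 8 & pw$freqs <= 30
  expect_lt(max(pw$power[sel]) / min(pw$power[sel]), 3)
  expect_error(welch_psd(rnorm(100), fs), "too short")
})

synthetic_psd <- function(b, chi, peaks, noise_sd = 0.02,
                          f = seq(3, 40, 0.5)) {
  y <- b - chi * log10(f)
  for (p in peaks) y <- y + p[1] * exp(-(f - p[2])^2 / (2 * p[3]^2))
  list(freqs = f, power = 10^(y + rnorm(length(f), 0, noise_sd)))
}

test_that("spectral model recovers planted aperiodic and peak parameters", {
  set.seed(21)
  m <- fit_spectral_model(synthetic_psd(1, 1, list(c(0.6, 11, 1.5))))
  expect_equal(unname(m$aperiodic["chi"]), 1, tolerance = 0.15)
  pk <- dominant_peak(m, c(8, 30))
  expect_true(pk$present)
  expect_lt(abs(pk$relative_power - 0.6), 0.1)
  expect_lt(abs(pk$center_frequency - 11), 0.5)
  expect_lt(abs(pk$frequency_width / 2 - 1.5), 0.5)
  # two peaks recovered, ordered by descending amplitude
  m2 <- fit_spectral_model(synthetic_psd(1, 1, list(c(0.6, 11, 1.5),
                                                    c(0.3, 22, 2))))
  expect_equal(nrow(m2$peaks), 2)
  expect_true(all(diff(m2$peaks$a) <= 0))
  expect_lt(abs(m2$peaks$c[1] - 11), 0.5)
  expect_lt(abs(m2$peaks$c[2] - 22), 1)
  # pure aperiodic spectrum yields no peaks
  m0 <- fit_spectral_model(synthetic_psd(1, 1.2, list()))
  expect_equal(nrow(m0$peaks), 0)
})

test_that("peak amplitude is invariant to rescaling the linear spectrum", {
  set.seed(22)
  psd <- synthetic_psd(1, 1, list(c(0.6, 11, 1.5)), noise_sd = 0)
  psd2 <- psd; psd2$power <- 37 * psd2$power
  m1 <- fit_spectral_model(psd); m2 <- fit_spectral_model(psd2)
  expect_equal(m1$peaks$a[1], m2$peaks$a[1], tolerance = 1e-6)
  expect_equal(unname(m2$aperiodic["b"] - m1$aperiodic["b"]), log10(37),
               tolerance = 1e-6)
})

test_that("fit error decreases weakly with the peak budget", {
  set.seed(23)
  psd <- synthetic_psd(1, 1, list(c(0.6, 11, 1.5), c(0.3, 22, 2)))
  errs <- vapply(c(0, 1, 2, 4), function(k)
    fit_spectral_model(psd, max_peaks = k)$fit_error, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("dominant peak selection restricts to the band and breaks ties toward mu", {
  model <- structure(list(
    aperiodic = c(b = 1, k = 0, chi = 1),
    peaks = tibble::tibble(a = c(0.6, 0.3), c = c(11, 22), w = c(1.5, 2)),
    fit_error = 0, r_squared = 1, range_hz = c(3, 40)),
    class = "spectral_model")
  pk <- dominant_peak(model, c(8, 30))
  expect_equal(pk$relative_power, 0.6)
  expect_equal(pk$center_frequency, 11)
  expect_equal(pk$frequency_width, 3.0)
  # out-of-band only
  model$peaks <- tibble::tibble(a = 0.5, c = 4, w = 1)
  expect_false(dominant_peak(model, c(8, 30))$present)
  # amplitude tie: lower center frequency (mu) wins
  model$peaks <- tibble::tibble(a = c(0.4, 0.4), c = c(24, 10), w = c(2, 2))
  expect_equal(dominant_peak(model, c(8, 30))$center_frequency, 10)
})
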