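#' Artifact-rejection criteria
#'
#' Thresholds for the four-stage epoch screening applied, in order:
#' absolute amplitude, linear trend, statistical improbability /
#' abnormal distribution, and abnormal spectrum.
#'
#' @param abs_amplitude_uV Reject when any sample of any channel exceeds
#'   this absolute amplitude (microvolts).
#' @param max_slope_uV_per_epoch Reject when the fitted straight line of
#'   any channel drifts by more than this over the epoch...
#' @param slope_r2_limit ...and the line's R-squared exceeds this limit
#'   (both conditions must hold).
#' @param improbability_sd Z-score limit (in SDs across trials) for the
#'   joint log-probability and kurtosis statistics, applied per channel
#'   and pooled over channels.
#' @param spectrum_dB Reject when any Welch-spectrum bin in the analysis
#'   band deviates from the across-trial mean spectrum by more than this
#'   many dB.
#' @param spectrum_band_hz Band over which the spectrum criterion is
#'   evaluated.
#' @return A `rejection_criteria` list.
#' @export
rejection_criteria <- function(abs_amplitude_uV = 25,
                               max_slope_uV_per_epoch = 50,
                               slope_r2_limit = 0.3,
                               improbability_sd = 5,
                               spectrum_dB = 25,
                               spectrum_band_hz = c(8, 30)) {
  crit <- list(abs_amplitude_uV = abs_amplitude_uV,
               max_slope_uV_per_epoch = max_slope_uV_per_epoch,
               slope_r2_limit = slope_r2_limit,
               improbability_sd = improbability_sd,
               spectrum_dB = spectrum_dB,
               spectrum_band_hz = spectrum_band_hz)
  if (any(unlist(crit) <= 0)) stop("all rejection thresholds must be positive")
  structure(crit, class = "rejection_criteria")
}

#' Construct an epoch set
#'
#' @param epochs Numeric array, trials x channels x time, microvolts.
#' @param window Length-2 numeric, epoch window in seconds relative to
#'   the prompt; half-open `[t_start, t_end)` with sample 0 at the prompt.
#' @param fs Sampling rate in Hz.
#' @param task_label Single task class label for all trials.
#' @param channel_names Channel labels.
#' @param kept_mask Logical per-trial mask (default all kept).
#' @param rejection_log Tibble with columns `trial` and `criterion`.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, window, fs, task_label, channel_names,
                      kept_mask = rep(TRUE, dim(epochs)[1]),
                      rejection_log = tibble::tibble(trial = integer(),
                                                     criterion = character())) {
  stopifnot(length(dim(epochs)) == 3,
            dim(epochs)[3] == round((window[2] - window[1]) * fs),
            dim(epochs)[2] == length(channel_names),
            length(kept_mask) == dim(epochs)[1])
  structure(list(epochs = epochs, window = window, fs = fs,
                 task_label = task_label, channel_names = channel_names,
                 kept_mask = kept_mask,
                 rejection_log = tibble::as_tibble(rejection_log)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> '%s': %d/%d trials kept, %d ch, [%g, %g) s @ %g Hz\n",
              x$task_label, sum(x$kept_mask), length(x$kept_mask),
              length(x$channel_names), x$window[1], x$window[2], x$fs))
  invisible(x)
}

#' Time axis of an epoch set
#' @param es An `epoch_set`.
#' @return Numeric vector of sample times in seconds (prompt at 0).
#' @export
epoch_times <- function(es) {
  n <- dim(es$epochs)[3]
  es$window[1] + (seq_len(n) - 1) / es$fs
}

#' Kept trials of an epoch set as an array
#' @param es An `epoch_set`.
#' @return Trials x channels x time array of the kept trials only.
#' @export
kept_epochs <- function(es) {
  es$epochs[es$kept_mask, , , drop = FALSE]
}

#' Extract task epochs from a continuous recording
#'
#' Cuts one epoch per event around each task prompt (sample 0 = prompt,
#' half-open window) and groups them by task label. Events whose window
#' would run past the record bounds are dropped and reported in the
#' `dropped` attribute.
#'
#' @param raw A [raw_recording()] with events.
#' @param window Epoch window in seconds, default `c(-1, 4)`.
#' @param labels Task labels to extract (default all non-rest labels
#'   present).
#' @return Named list of [epoch_set()] objects, one per label, with a
#'   `dropped` attribute (tibble of dropped events).
#' @export
extract_epochs <- function(raw, window = c(-1, 4), labels = NULL) {
  ev <- raw$events
  if (is.null(labels))
    labels <- setdiff(unique(ev$label), "rest")
  if (!length(labels)) stop("no task labels to extract")
  n_time <- round((window[2] - window[1]) * raw$fs)
  offset <- round(window[1] * raw$fs)
  dropped <- tibble::tibble(onset_sample = integer(), label = character())
  out <- list()
  for (lab in labels) {
    onsets <- ev$onset_sample[ev$label == lab]
    if (!length(onsets))
      stop("no events with label '", lab, "' in the recording")
    first <- onsets + offset
    ok <- first >= 1 & (first + n_time - 1) <= ncol(raw$samples)
    if (any(!ok))
      dropped <- dplyr::bind_rows(dropped,
        tibble::tibble(onset_sample = onsets[!ok], label = lab))
    onsets <- onsets[ok]
    arr <- array(0, c(length(onsets), nrow(raw$samples), n_time))
    for (i in seq_along(onsets)) {
      cols <- (onsets[i] + offset):(onsets[i] + offset + n_time - 1)
      arr[i, , ] <- raw$samples[, cols]
    }
    out[[lab]] <- epoch_set(arr, window, raw$fs, lab, raw$channel_names)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Reject artifact epochs
#'
#' Applies the four rejection criteria in order (amplitude, trend,
#' improbability/distribution, spectrum) to the kept trials of an epoch
#' set. Each rejected trial is logged with the first criterion that
#' fired. Reference statistics for the improbability and spectrum stages
#' are computed over the trials surviving the preceding stages, matching
#' sequential screening.
#'
#' @param es An [epoch_set()].
#' @param crit A [rejection_criteria()].
#' @return The epoch set with `kept_mask` and `rejection_log` updated.
#'   If every trial ends up rejected a warning is raised and the empty
#'   set returned.
#' @export
reject_epochs <- function(es, crit = rejection_criteria()) {
  if (!sum(es$kept_mask)) stop("epoch set has no kept trials")
  idx <- which(es$kept_mask)
  x <- es$epochs[idx, , , drop = FALSE]
  nt <- dim(x)[1]
  fired <- rep(NA_character_, nt)

  # 1: absolute amplitude
  amp <- apply(abs(x), 1, max)
  fired[is.na(fired) & amp > crit$abs_amplitude_uV] <- "amplitude"

  # 2: linear trend (per channel OLS drift over the epoch + R^2 gate)
  n_time <- dim(x)[3]
  tt <- seq_len(n_time) - (n_time + 1) / 2
  sxx <- sum(tt^2)
  for (i in which(is.na(fired))) {
    xm <- x[i, , ] - rowMeans(x[i, , , drop = FALSE], dims = 1)
    slope <- (xm %*% tt) / sxx
    drift <- abs(slope) * (n_time - 1)
    ssr <- drop(slope)^2 * sxx
    sst <- rowSums(xm^2)
    r2 <- ifelse(sst > 0, ssr / sst, 0)
    if (any(drift > crit$max_slope_uV_per_epoch & r2 > crit$slope_r2_limit))
      fired[i] <- "trend"
  }

  # 3: improbability (joint log-probability) and distribution (kurtosis)
  surv <- which(is.na(fired))
  if (length(surv) >= 4) {
    jp <- .jointprob_stats(x[surv, , , drop = FALSE])
    bad <- .z_exceeds(jp, crit$improbability_sd)
    fired[surv[bad]] <- "improbability"
    surv <- which(is.na(fired))
    ku <- .kurtosis_stats(x[surv, , , drop = FALSE])
    bad <- .z_exceeds(ku, crit$improbability_sd)
    fired[surv[bad]] <- "distribution"
  }

  # 4: abnormal spectrum relative to the across-trial mean (dB)
  surv <- which(is.na(fired))
  if (length(surv) >= 4) {
    ps <- .epoch_band_spectra(x[surv, , , drop = FALSE], es$fs,
                              crit$spectrum_band_hz)
    ref <- apply(ps, c(2, 3), mean)
    dev <- 10 * abs(sweep(log10(ps), c(2, 3), log10(ref)))
    bad <- apply(dev, 1, max) > crit$spectrum_dB
    fired[surv[bad]] <- "spectrum"
  }

  rejected <- which(!is.na(fired))
  if (length(rejected)) {
    es$kept_mask[idx[rejected]] <- FALSE
    es$rejection_log <- dplyr::bind_rows(
      es$rejection_log,
      tibble::tibble(trial = idx[rejected], criterion = fired[rejected]))
  }
  if (!sum(es$kept_mask))
    warning("all trials rejected for task '", es$task_label, "'")
  es
}

# per-trial z-scored statistic matrix -> which trials exceed the limit,
# testing each channel and the channel-pooled value
.z_exceeds <- function(stat, limit) {
  z <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  zc <- apply(stat, 2, z)                      # trials x channels
  if (is.null(dim(zc))) zc <- matrix(zc, nrow = nrow(stat))
  zp <- z(rowMeans(stat))                      # pooled across channels
  apply(abs(zc), 1, max) > limit | abs(zp) > limit
}

# mean log empirical density of each trial's samples, per channel
.jointprob_stats <- function(x) {
  nt <- dim(x)[1]; nc <- dim(x)[2]
  out <- matrix(0, nt, nc)
  for (c in seq_len(nc)) {
    pool <- as.numeric(x[, c, ])
    br <- seq(min(pool), max(pool), length.out = 101)
    br[1] <- br[1] - 1e-9; br[101] <- br[101] + 1e-9
    dens <- tabulate(findInterval(pool, br), nbins = 100) / length(pool)
    dens[dens == 0] <- 1 / length(pool)
    for (i in seq_len(nt)) {
      b <- findInterval(x[i, c, ], br)
      b[b < 1] <- 1; b[b > 100] <- 100
      out[i, c] <- -mean(log(dens[b]))         # surprise: high = improbable
    }
  }
  out
}

.kurtosis_stats <- function(x) {
  nt <- dim(x)[1]; nc <- dim(x)[2]
  out <- matrix(0, nt, nc)
  for (i in seq_len(nt)) for (c in seq_len(nc)) {
    v <- x[i, c, ]
    m <- mean(v); s2 <- mean((v - m)^2)
    out[i, c] <- if (s2 > 0) mean((v - m)^4) / s2^2 - 3 else 0
  }
  out
}

# trials x channels x bins Welch band power for the spectrum criterion
# (all trial/channel series transformed together, one FFT per segment)
.epoch_band_spectra <- function(x, fs, band) {
  nt <- dim(x)[1]; nc <- dim(x)[2]; ns <- dim(x)[3]
  nper <- fs                                   # 1-s segments
  nover <- floor(nper / 2)
  starts <- seq(1, ns - nper + 1, by = nper - nover)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  u <- sum(win^2)
  nf <- floor(nper / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / nper
  keep <- which(freqs >= band[1] & freqs <= band[2])
  M <- matrix(aperm(x, c(3, 2, 1)), ns)        # time x (channel*trial)
  acc <- matrix(0, length(keep), ncol(M))
  for (s in starts) {
    seg <- M[s:(s + nper - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * win
    p <- Mod(stats::mvfft(seg))^2 / (fs * u)
    acc <- acc + 2 * p[keep, , drop = FALSE]
  }
  acc <- acc / length(starts)
  aperm(array(acc, c(length(keep), nc, nt)), c(3, 2, 1)) +
    .Machine$double.xmin
}
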