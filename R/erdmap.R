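#' Morlet time-frequency decomposition of epoched activations
#'
#' Per-trial squared magnitude of a complex Morlet wavelet transform
#' (Gaussian envelope, `n_cycles` cycles, FFT convolution), averaged
#' into resels of `resel_ms` x 1 Hz for downstream statistics. Samples
#' where the wavelet support overruns the epoch are flagged invalid per
#' frequency.
#'
#' @param activations Trials x time matrix (one component), or a
#'   trials x channels x time array with `channel` selecting a slice.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz (default 8-30 in 1 Hz steps).
#' @param n_cycles Wavelet cycles (temporal SD `n_cycles / (2 pi f)`).
#' @param window Epoch window in seconds relative to the prompt.
#' @param resel_ms Resel width in milliseconds.
#' @param channel Component/channel index when `activations` is 3-D.
#' @return Object of class `tf_map`: `power` (trials x freqs x resels,
#'   linear), `freqs`, `times` (resel centers, s), `valid` (freqs x
#'   resels logical), `fs`, `window`.
#' @export
morlet_tf <- function(activations, fs, freqs = 8:30, n_cycles = 3,
                      window = c(-1, 4), resel_ms = 25, channel = NULL) {
  if (length(dim(activations)) == 3) {
    if (is.null(channel)) stop("supply `channel` for a 3-D activation array")
    activations <- activations[, channel, ]
  }
  if (is.null(dim(activations))) activations <- matrix(activations, 1)
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("analysis frequencies must lie in (0, fs/2)")
  nt <- nrow(activations); ns <- ncol(activations)
  half_max <- ceiling(3.5 * n_cycles / (2 * pi * min(freqs)) * fs)
  if (ns <= 2 * half_max)
    stop("epoch too short for the lowest-frequency wavelet")
  rs <- max(1L, round(resel_ms / 1000 * fs))
  n_res <- floor(ns / rs)
  nfft <- stats::nextn(ns + 2 * half_max + 1, 2)
  FX <- stats::mvfft(rbind(t(activations), matrix(0, nfft - ns, nt)))
  power <- array(NA_real_, c(nt, length(freqs), n_res))
  valid <- matrix(FALSE, length(freqs), n_res)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sd_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sd_t * fs)
    tw <- (-half:half) / fs
    w <- exp(-tw^2 / (2 * sd_t^2)) * exp(2i * pi * f * tw)
    w <- w / sqrt(sum(Mod(w)^2))
    wpad <- complex(length.out = nfft)
    wpad[1:(half + 1)] <- w[(half + 1):(2 * half + 1)]
    wpad[(nfft - half + 1):nfft] <- w[1:half]
    FW <- stats::fft(wpad)
    conv <- stats::mvfft(FX * FW, inverse = TRUE) / nfft
    pw <- Mod(conv[1:ns, , drop = FALSE])^2      # time x trials
    # average into resels
    pr <- rowsum(pw[1:(n_res * rs), , drop = FALSE],
                 rep(seq_len(n_res), each = rs)) / rs
    power[, fi, ] <- t(pr)
    ok <- rep(TRUE, ns)
    ok[1:half] <- FALSE; ok[(ns - half + 1):ns] <- FALSE
    valid[fi, ] <- rowsum(as.numeric(ok[1:(n_res * rs)]),
                          rep(seq_len(n_res), each = rs)) == rs
  }
  times <- window[1] + (seq_len(n_res) - 0.5) * rs / fs
  structure(list(power = power, freqs = freqs, times = times,
                 valid = valid, fs = fs, window = window),
            class = "tf_map")
}

#' Baseline-relative ERD/ERS percentage
#'
#' Percent power change of the trial-averaged time-frequency map
#' relative to the per-frequency mean power over the reference interval,
#' `(P - R) / R * 100`. The scalar summary is the plain (unrectified)
#' mean of the band-averaged percent change over the task interval: for
#' a contralateral ERD component it is negative, for an ipsilateral ERS
#' component positive.
#'
#' @param tf A [morlet_tf()] map.
#' @param baseline Reference interval in seconds, default `c(-1, 0)`.
#' @param band Band for the scalar summary, default the full map band.
#' @param task_window Interval for the scalar summary, default `c(0, 4)`.
#' @return Object of class `erd_series`: `percent` (freqs x resels),
#'   `baseline_power` (per frequency), `scalar_percent` (= both the
#'   scalar ERD% and ERS% value, whose role is decided by its sign at
#'   the component level), `freqs`, `times`.
#' @export
erd_percent <- function(tf, baseline = c(-1, 0), band = NULL,
                        task_window = c(0, 4)) {
  if (is.null(band)) band <- range(tf$freqs)
  bcols <- tf$times >= baseline[1] & tf$times < baseline[2]
  if (!any(bcols)) stop("baseline interval not inside the time grid")
  P <- apply(tf$power, c(2, 3), mean)               # freqs x resels
  R <- vapply(seq_along(tf$freqs), function(fi) {
    use <- bcols & tf$valid[fi, ]
    if (!any(use)) return(NA_real_)
    mean(P[fi, use])
  }, numeric(1))
  if (any(!is.na(R) & R <= 0)) stop("zero baseline power in the analysis band")
  percent <- sweep(sweep(P, 1, R), 1, R, "/") * 100
  percent[!tf$valid] <- NA_real_
  # scalar: percent change of the band power (band-averaged power first,
  # then baseline ratio), averaged over the task interval
  brow <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  # only columns where every band row is valid, so the band composition
  # does not change over time (edge margins differ per frequency)
  common <- colSums(!tf$valid[brow, , drop = FALSE]) == 0
  Pb <- colMeans(P[brow, , drop = FALSE])
  Rb <- mean(Pb[bcols & common])
  tcols <- tf$times >= task_window[1] & tf$times < task_window[2]
  scalar <- mean((Pb[tcols & common] - Rb) / Rb) * 100
  structure(list(percent = percent, baseline_power = R,
                 scalar_percent = scalar, freqs = tf$freqs,
                 times = tf$times, band = band, task_window = task_window),
            class = "erd_series")
}

#' Pseudo-T significance map with FDR correction
#'
#' For every resel, a pseudo-T statistic contrasts its per-trial power
#' against the trial's mean baseline power (paired mean difference over
#' its standard error). The null distribution is built per frequency by
#' extensive random sampling within the reference interval: each
#' resample draws, per trial, a pseudo test value from the baseline
#' resels and a pseudo baseline as the mean of a with-replacement
#' resample of the trial's 100 ms baseline blocks. Two-sided p-values
#' are Benjamini-Hochberg corrected across all valid resels.
#'
#' @param tf A [morlet_tf()] map (>= 10 trials recommended).
#' @param baseline Reference interval in seconds.
#' @param n_resamples Number of random resamples (default 200; fewer
#'   than 50 warns).
#' @param alpha FDR level for the significance mask.
#' @param block_s Baseline block length for the resampled baseline mean.
#' @param seed Resampling seed (fixed default: identical mask on rerun).
#' @return Object of class `significance_map`: `pseudo_t`, `p_values`,
#'   `q_values`, `sig_mask` (freqs x resels), `freqs`, `times`, `alpha`.
#' @export
pseudo_t_significance <- function(tf, baseline = c(-1, 0), n_resamples = 200,
                                  alpha = 0.05, block_s = 0.1, seed = 1) {
  if (n_resamples < 50) warning("fewer than 50 resamples; p-values are coarse")
  if (dim(tf$power)[1] < 2) stop("pseudo-T statistics need at least 2 trials")
  if (dim(tf$power)[1] < 10)
    warning("fewer than 10 trials; pseudo-T statistics are unstable")
  set.seed(seed)
  nf <- length(tf$freqs); nres <- length(tf$times)
  n <- dim(tf$power)[1]
  Tmat <- matrix(NA_real_, nf, nres)
  Pmat <- matrix(NA_real_, nf, nres)
  resel_s <- diff(tf$times[1:2])
  bsize <- max(1L, round(block_s / resel_s))
  for (fi in seq_len(nf)) {
    bcols <- which(tf$times >= baseline[1] & tf$times < baseline[2] &
                     tf$valid[fi, ])
    vcols <- which(tf$valid[fi, ])
    if (length(bcols) < 2 || !length(vcols)) next
    X <- tf$power[, fi, , drop = TRUE]
    B <- X[, bcols, drop = FALSE]
    bbar <- rowMeans(B)
    D <- X[, vcols, drop = FALSE] - bbar
    m <- colMeans(D)
    se <- apply(D, 2, stats::sd) / sqrt(n)
    Tobs <- m / pmax(se, .Machine$double.eps)
    # null distribution from baseline resampling
    nb <- length(bcols)
    n_blk <- max(1L, floor(nb / bsize))
    blk_id <- rep(seq_len(n_blk), each = bsize, length.out = nb)
    BM <- t(rowsum(t(B), blk_id) / as.numeric(table(blk_id)))  # trials x blocks
    R <- n_resamples
    ridx <- function(k, m) floor(stats::runif(k) * m) + 1  # fast index draw
    xstar <- matrix(B[cbind(rep(seq_len(n), R), ridx(n * R, nb))], n, R)
    bstar <- matrix(0, n, R)
    for (bb in seq_len(n_blk))
      bstar <- bstar + matrix(BM[cbind(rep(seq_len(n), R),
                                       ridx(n * R, n_blk))], n, R)
    dstar <- xstar - bstar / n_blk
    mu <- colMeans(dstar)
    sds <- sqrt(pmax(colSums(dstar^2) - n * mu^2, 0) / (n - 1))
    Tnull <- mu / pmax(sds / sqrt(n), .Machine$double.eps)
    Pmat[fi, vcols] <- vapply(abs(Tobs), function(tv)
      (1 + sum(abs(Tnull) >= tv)) / (n_resamples + 1), numeric(1))
    Tmat[fi, vcols] <- Tobs
  }
  ok <- !is.na(Pmat)
  q <- Pmat
  q[ok] <- stats::p.adjust(Pmat[ok], method = "BH")
  mask <- !is.na(q) & q <= alpha
  structure(list(pseudo_t = Tmat, p_values = Pmat, q_values = q,
                 sig_mask = mask, freqs = tf$freqs, times = tf$times,
                 alpha = alpha),
            class = "significance_map")
}

#' Signed 4-connected regions of a significance map
#'
#' Labels the significant resels into 4-connected components (adjacency
#' along time and frequency only, not diagonals) and summarizes each
#' region: sign (ERD when the mean percent change of its members is
#' negative, ERS when positive), area in resels, latency (earliest time
#' among member resels) and mean change.
#'
#' @param sig A [pseudo_t_significance()] map (or any list with
#'   `sig_mask`, `times`).
#' @param percent_map Freqs x resels percent-change matrix (from
#'   [erd_percent()]).
#' @return Tibble with columns `region`, `sign`, `area`, `latency_s`,
#'   `mean_change`; zero rows when nothing is significant.
#' @export
connected_regions <- function(sig, percent_map) {
  lab <- .label_4connected(sig$sig_mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    members <- which(lab == id, arr.ind = TRUE)
    mc <- mean(percent_map[lab == id], na.rm = TRUE)
    tibble::tibble(region = id,
                   sign = if (mc < 0) "ERD" else "ERS",
                   area = nrow(members),
                   latency_s = min(sig$times[members[, 2]]),
                   mean_change = mc)
  })
  if (!length(rows))
    return(tibble::tibble(region = integer(), sign = character(),
                          area = integer(), latency_s = numeric(),
                          mean_change = numeric()))
  dplyr::bind_rows(rows)
}

#' Largest connected region of a given sign
#'
#' @param regions A [connected_regions()] tibble.
#' @param sign `"ERD"` or `"ERS"`.
#' @return One-row tibble (largest area; ties by larger absolute mean
#'   change), or a zero-area placeholder row when no region of that
#'   sign exists.
#' @export
largest_region <- function(regions, sign = c("ERD", "ERS")) {
  sign <- match.arg(sign)
  r <- regions[regions$sign == sign, ]
  if (!nrow(r))
    return(tibble::tibble(region = NA_integer_, sign = sign, area = 0L,
                          latency_s = NA_real_, mean_change = NA_real_))
  r <- r[order(-r$area, -abs(r$mean_change)), ]
  r[1, ]
}

# iterative queue-based 4-connected labeling of a logical matrix
.label_4connected <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > nc) next
        k <- (nb[2] - 1L) * nr + nb[1]
        if (mask[k] && lab[k] == 0L) {
          lab[k] <- nextlab
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}
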