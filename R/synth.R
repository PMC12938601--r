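#' Subject profile for the synthetic-data generator
#'
#' Describes one simulated participant: how deeply each hemisphere's mu
#' source desynchronizes during contralateral-hand imagery (`erd_depth`,
#' fractional power drop), how strongly the ipsilateral source
#' synchronizes (`ers_gain`, fractional power rise over a 1-2 s burst),
#' oscillation center frequencies, the aperiodic background, and sensor
#' noise. The four canonical proficiency groups are encoded as defaults:
#' `good` modulates for both hands, `LgoodRpoor` only during left-hand
#' imagery, `LpoorRgood` only during right-hand imagery, `poor` barely at
#' all. Source oscillation amplitude is coupled to the modulation
#' strength, so proficient profiles also carry more prominent mu peaks.
#'
#' @param group_label One of `"good"`, `"LgoodRpoor"`, `"LpoorRgood"`,
#'   `"poor"`.
#' @param erd_depth Named numeric `c(left = , right = )`: fractional
#'   contralateral power drop during imagery of that hand, in `[0, 1)`.
#' @param ers_gain Named numeric `c(left = , right = )`: fractional
#'   ipsilateral power rise, `>= 0`.
#' @param mu_contra_hz,mu_ipsi_hz Center frequencies of the ERD (lower
#'   mu) and ERS (upper mu) sources.
#' @param aperiodic Named vector `c(b = , k = , chi = )` of the 1/f
#'   background in log10(power) form.
#' @param sensor_noise_sd Additive white sensor noise SD, microvolts.
#' @param artifact_rate Per-epoch probability of an injected in-band
#'   artifact burst.
#' @param seed Integer seed making the subject reproducible.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(group_label = c("good", "LgoodRpoor",
                                            "LpoorRgood", "poor"),
                            erd_depth = NULL, ers_gain = NULL,
                            mu_contra_hz = 11, mu_ipsi_hz = 12,
                            aperiodic = c(b = 0, k = 0, chi = 1.2),
                            sensor_noise_sd = 0.4,
                            artifact_rate = 0.1,
                            seed = 1) {
  group_label <- match.arg(group_label)
  defaults <- list(
    good       = list(d = c(left = 0.5,  right = 0.5),
                      g = c(left = 0.6,  right = 0.6)),
    LgoodRpoor = list(d = c(left = 0.5,  right = 0.1),
                      g = c(left = 0.6,  right = 0.08)),
    LpoorRgood = list(d = c(left = 0.1,  right = 0.5),
                      g = c(left = 0.08, right = 0.6)),
    poor       = list(d = c(left = 0.08, right = 0.08),
                      g = c(left = 0.05, right = 0.05)))[[group_label]]
  if (is.null(erd_depth)) erd_depth <- defaults$d
  if (is.null(ers_gain)) ers_gain <- defaults$g
  name2 <- function(v) {
    stopifnot(length(v) == 2)
    if (is.null(names(v))) names(v) <- c("left", "right")
    v[c("left", "right")]
  }
  erd_depth <- name2(erd_depth); ers_gain <- name2(ers_gain)
  stopifnot(all(erd_depth >= 0 & erd_depth < 1), all(ers_gain >= 0),
            mu_contra_hz >= 8, mu_contra_hz <= 30,
            mu_ipsi_hz >= 8, mu_ipsi_hz <= 30)
  structure(list(group_label = group_label, erd_depth = erd_depth,
                 ers_gain = ers_gain, mu_contra_hz = mu_contra_hz,
                 mu_ipsi_hz = mu_ipsi_hz, aperiodic = aperiodic,
                 sensor_noise_sd = sensor_noise_sd,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "subject_profile")
}

# deterministic 31-bit sub-seed
.fork_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

# circular Gaussian smoothing via FFT (kernel sd in samples)
.smooth_gauss <- function(x, sd_samples) {
  n <- length(x)
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  g <- exp(-2 * (pi * f * sd_samples)^2)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# unit-RMS bursty narrowband oscillation at center_hz (~2 Hz bandwidth,
# lognormal burst envelope with ~0.3 s coherence, as mu bursts show)
.narrowband_source <- function(n, fs, center_hz, bandwidth_hz = 2.5,
                               burst_sigma = 0.45, burst_coh_s = 0.15) {
  sd_t <- fs / (2 * pi * bandwidth_hz)
  zr <- .smooth_gauss(stats::rnorm(n), sd_t)
  zi <- .smooth_gauss(stats::rnorm(n), sd_t)
  t <- (seq_len(n) - 1) / fs
  x <- zr * cos(2 * pi * center_hz * t) - zi * sin(2 * pi * center_hz * t)
  s <- burst_coh_s * fs
  z <- .smooth_gauss(stats::rnorm(n), s) * sqrt(2 * sqrt(pi) * s)
  x <- x * exp(burst_sigma * z)
  x / stats::sd(x)
}

# unit-RMS 1/f-like background realized in the spectral domain
.aperiodic_source <- function(n, fs, ap) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  amp <- sqrt(10^(ap["b"] - log10(ap["k"] + f^ap["chi"])))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full[1:n], inverse = TRUE))
  x / stats::sd(x)
}

#' Simulate one subject's motor-imagery recording
#'
#' Builds a continuous 30-channel recording at `fs` Hz containing
#' interleaved left- and right-hand imagery trials (4.2 s imagery
#' separated by 4.2 s rest). Each hemisphere hosts a lower-mu ERD source
#' whose envelope drops by the profile's `erd_depth` during
#' contralateral-hand imagery, and an upper-mu ERS source whose envelope
#' rises by `ers_gain` over a random 1-2 s sub-interval of the imagery
#' period during ipsilateral-hand imagery. Aperiodic 1/f background
#' sources, all mixed by the concentric-sphere forward solution, and
#' white sensor noise complete the model; occasional epochs receive an
#' in-band artifact burst.
#'
#' @param profile A [subject_profile()].
#' @param n_trials_per_hand Trials per hand (default 45: three runs of
#'   15).
#' @param fs Sampling rate in Hz.
#' @param hm Optional shared [head_model()] (built if omitted).
#' @return List with `recording` (a [raw_recording()]) and
#'   `ground_truth`: tibble `sources` (role, hand, position, mixing
#'   column index), `mixing` matrix, task-source activation matrix
#'   `task_sources`, squared envelope matrix `task_envelopes` (power
#'   modulation factors), events, and the profile.
#' @export
simulate_subject <- function(profile, n_trials_per_hand = 45, fs = 160,
                             hm = NULL) {
  if (n_trials_per_hand < 2) stop("need at least 2 trials per hand")
  if (is.null(hm)) hm <- head_model()
  set.seed(profile$seed)
  trial_s <- 8.4
  n_trials <- 2L * n_trials_per_hand
  hands <- sample(rep(c("left", "right"), n_trials_per_hand))
  onsets_t <- 4.2 + (seq_len(n_trials) - 1) * trial_s
  total_s <- ceiling(n_trials * trial_s + 4.2)
  n <- total_s * fs
  onsets <- as.integer(round(onsets_t * fs)) + 1L

  jit <- function(x, a) x + stats::runif(length(x), -a, a)
  src <- tibble::tibble(
    role = c("erd", "erd", "ers", "ers"),
    hand = c("right", "left", "left", "right"),    # hand whose imagery modulates
    hemisphere = c("left", "right", "left", "right"),
    x = jit(c(-40, 40, -34, 34), 3),
    y = jit(c(-22, -22, -40, -40), 3),   # ERS sources more posterior, so
    z = jit(c(46, 46, 38, 38), 3))       # the two mu sources per
                                         # hemisphere stay separable

  # base oscillation amplitude coupled to modulation strength: ERD
  # sources modulate deeply but sit at modest amplitude; ERS (upper mu)
  # amplitude scales strongly with proficiency, so weakly synchronizing
  # subjects also lack a prominent upper-mu peak
  amp_of <- function(role, hand) {
    if (role == "erd") 2.6 * (0.6 + 0.8 * profile$erd_depth[[hand]])
    else 4.2 * (0.1 + 1.5 * min(profile$ers_gain[[hand]], 1))
  }
  src$amp <- mapply(amp_of, src$role, src$hand)
  src$center_hz <- ifelse(src$role == "erd", profile$mu_contra_hz,
                          profile$mu_ipsi_hz)

  task_sources <- matrix(0, 4, n)
  task_env2 <- matrix(1, 4, n)          # squared (power) envelopes
  tvec <- (seq_len(n) - 1) / fs
  ramp <- function(t0, t1, r = 0.1) {
    # cosine-ramped indicator of [t0, t1] on the global time axis
    up <- pmin(pmax((tvec - t0) / r, 0), 1)
    dn <- pmin(pmax((t1 - tvec) / r, 0), 1)
    0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * dn))
  }
  ers_windows <- vector("list", 4)
  for (s in 1:4) {
    osc <- .narrowband_source(n, fs, src$center_hz[s])
    env2 <- rep(1, n)
    for (k in which(hands == src$hand[s])) {
      t0 <- onsets_t[k]
      if (src$role[s] == "erd") {
        ind <- ramp(t0, t0 + 4.2)
        env2 <- env2 - profile$erd_depth[[src$hand[s]]] * ind
      } else {
        dur <- stats::runif(1, 1, 2)
        b0 <- stats::runif(1, 0, 4 - dur)
        ind <- ramp(t0 + b0, t0 + b0 + dur)
        env2 <- env2 + profile$ers_gain[[src$hand[s]]] * ind
        ers_windows[[s]] <- rbind(ers_windows[[s]], c(trial = k, start = b0, dur = dur))
      }
    }
    task_env2[s, ] <- env2
    # each cortical patch produces its oscillation plus its own 1/f
    # background, both modulated by the task envelope: the component's
    # percent change then reflects the planted depth undiluted, while its
    # spectral peak height encodes the oscillation-to-background ratio.
    # ERD (lower mu) patches are broader-spectrum than the cleaner
    # upper-mu ERS patches.
    bb <- if (src$role[s] == "erd") 4.5 else 0.8
    task_sources[s, ] <- (osc * src$amp[s] +
                            bb * .aperiodic_source(n, fs, profile$aperiodic)) *
      sqrt(pmax(env2, 0))
  }

  n_bg <- 8
  ss <- hm$source_space
  bg_pool <- ss[ss$region == "non-motor", ]
  bg_idx <- sample(nrow(bg_pool), n_bg)
  bg_pos <- as.matrix(bg_pool[bg_idx, c("x", "y", "z")])
  bg_sources <- t(vapply(seq_len(n_bg), function(i)
    1.0 * .aperiodic_source(n, fs, profile$aperiodic), numeric(n)))

  all_pos <- rbind(as.matrix(src[, c("x", "y", "z")]), bg_pos)
  mix <- vapply(seq_len(nrow(all_pos)), function(i) {
    mom <- stats::rnorm(3)
    col <- forward_dipole(hm, all_pos[i, ], mom)
    col / sqrt(sum(col^2))
  }, numeric(nrow(hm$electrodes)))

  samples <- mix %*% rbind(task_sources, bg_sources) +
    matrix(stats::rnorm(nrow(mix) * n, sd = profile$sensor_noise_sd),
           nrow(mix), n)

  # in-band artifact bursts on a random channel of unlucky epochs
  n_art <- stats::rbinom(1, n_trials, profile$artifact_rate)
  art_trials <- sample(n_trials, n_art)
  for (k in art_trials) {
    ch <- sample(nrow(mix), 1)
    i0 <- onsets[k] + sample(0:(3 * fs), 1)
    ii <- i0:(i0 + fs - 1)
    samples[ch, ii] <- samples[ch, ii] +
      40 * sin(2 * pi * 15 * tvec[ii]) * sin(pi * seq(0, 1, length.out = fs))^2
  }

  events <- tibble::tibble(onset_sample = onsets, label = hands)
  rec <- raw_recording(samples, rownames(hm$electrodes), fs, events)
  gt <- list(sources = src, mixing = mix, task_sources = task_sources,
             task_envelopes = task_env2, events = events,
             artifact_trials = sort(art_trials),
             ers_windows = ers_windows, profile = profile)
  list(recording = rec, ground_truth = gt)
}

#' Ground-truth ERD/ERS percentage of a planted source
#'
#' Computes the baseline-relative percent power change of a planted task
#' source directly from its known squared envelope (the generator's
#' ground truth), averaged over trials: an independent oracle for the
#' time-frequency pipeline.
#'
#' @param gt `ground_truth` element of [simulate_subject()].
#' @param source_index Row of `gt$sources`.
#' @param task_window Seconds relative to the prompt, default `c(0, 4)`.
#' @param baseline Seconds relative to the prompt, default `c(-1, 0)`.
#' @return Scalar mean percent change over that source's trials.
#' @export
planted_percent_change <- function(gt, source_index,
                                   task_window = c(0, 4),
                                   baseline = c(-1, 0)) {
  fs <- 160
  env2 <- gt$task_envelopes[source_index, ]
  hand <- gt$sources$hand[source_index]
  onsets <- gt$events$onset_sample[gt$events$label == hand]
  vals <- vapply(onsets, function(o) {
    task <- env2[(o + round(task_window[1] * fs)):(o + round(task_window[2] * fs) - 1)]
    base <- env2[(o + round(baseline[1] * fs)):(o + round(baseline[2] * fs) - 1)]
    (mean(task) - mean(base)) / mean(base) * 100
  }, numeric(1))
  mean(vals)
}

#' Generate a cohort of subject profiles
#'
#' Deterministically allocates `n_subjects` across the four proficiency
#' groups by largest-remainder rounding of `proportions`, and draws
#' per-subject jittered profiles (modulation depths, center frequencies,
#' aperiodic exponent) from documented ranges under per-subject seeds
#' forked from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param proportions Named fractions over the four groups; must sum
#'   to 1.
#' @param seed Cohort seed.
#' @return Tibble with `subject_id`, `group_label` and a `profile`
#'   list-column; pass rows to [simulate_subject()].
#' @export
make_cohort <- function(n_subjects,
                        proportions = c(good = 0.25, LgoodRpoor = 0.275,
                                        LpoorRgood = 0.117, poor = 0.358),
                        seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("group proportions must sum to 1 (got ", sum(proportions), ")")
  groups <- names(proportions)
  if (n_subjects < sum(proportions > 0))
    stop("fewer subjects than groups with nonzero proportion")
  quota <- proportions * n_subjects
  counts <- floor(quota)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(groups, counts)
  profiles <- lapply(seq_len(n_subjects), function(i) {
    sseed <- .fork_seed(seed, i)
    set.seed(sseed)
    base <- subject_profile(labels[i], seed = sseed)
    j <- function(x, lo, hi) pmin(0.95, pmax(0, x * stats::runif(length(x), lo, hi)))
    subject_profile(
      labels[i],
      erd_depth = j(base$erd_depth, 0.85, 1.15),
      ers_gain = pmax(0, base$ers_gain * stats::runif(2, 0.85, 1.15)),
      # jitter lower mu, then place upper mu a band above it: the two
      # rhythms stay spectrally distinct in every subject
      mu_contra_hz = mu0 <- base$mu_contra_hz + stats::runif(1, -0.4, 0.4),
      mu_ipsi_hz = mu0 + stats::runif(1, 1.0, 1.6),
      aperiodic = c(b = 0, k = 0,
                    chi = unname(base$aperiodic["chi"] + stats::runif(1, -0.2, 0.2))),
      seed = .fork_seed(sseed, 97))
  })
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                 group_label = labels, profile = profiles)
}
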