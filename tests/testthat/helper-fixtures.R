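# Shared fixtures built in code. The head model is expensive enough to
# build once per test run; everything else is cheap and seeded locally.

shared_head_model <- local({
  hm <- NULL
  function() {
    if (is.null(hm)) hm <<- head_model()
    hm
  }
})

# trials x time matrix of bursty narrowband oscillation with a given
# squared-envelope function of epoch time (prompt at 0)
make_envelope_trials <- function(envfun, n_trials = 40, fs = 160,
                                 window = c(-1, 4), f0 = 11,
                                 noise_sd = 0) {
  ns <- round(diff(window) * fs)
  tt <- window[1] + (seq_len(ns) - 1) / fs
  x <- t(vapply(seq_len(n_trials), function(i)
    erdica:::.narrowband_source(ns, fs, f0) * sqrt(envfun(tt)),
    numeric(ns)))
  if (noise_sd > 0) x <- x + matrix(rnorm(n_trials * ns, sd = noise_sd),
                                    n_trials)
  x
}

# independent recursive flood-fill labeling oracle (4-connectivity)
floodfill_label_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fill <- function(i, j) {
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- p[1]; j <- p[2]
      if (i < 1 || i > nr || j < 1 || j > nc) next
      if (!mask[i, j] || lab[i, j] != 0L) next
      lab[i, j] <<- cur
      stack <- c(stack, list(c(i - 1L, j), c(i + 1L, j),
                             c(i, j - 1L), c(i, j + 1L)))
    }
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      fill(i, j)
    }
  }
  lab
}

# canonical form of a labeling: per-cell multiset of component sizes and
# a relabeling by first occurrence, so two labelings can be compared
canonical_labels <- function(lab) {
  seen <- unique(as.vector(t(lab)))
  seen <- seen[seen != 0L]
  map <- integer(max(c(0L, seen)))
  map[seen] <- seq_along(seen)
  out <- lab
  out[lab != 0L] <- map[lab[lab != 0L]]
  out
}

# feature cohort with a known linear ClassDis relationship
make_feature_cohort <- function(n = 40, seed = 1, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * 8), n)
  colnames(X) <- erdica:::.feature_cols
  f <- tibble::as_tibble(X)
  f$subject_id <- sprintf("S%03d", seq_len(n))
  f$classdis <- 1 - 0.3 * f$erd_pct_lh + 0.25 * f$rel_ers_power_rh +
    rnorm(n, sd = noise)
  f
}

# hand-built selection-rule candidate rows (profiles tibble shape)
make_profile_row <- function(ic, x = 40, y = -25, z = 50,
                             relative_power = 0.5, peak_present = TRUE,
                             center_frequency = 11, erd_area = 0L,
                             ers_area = 0L, erd_mean_change = -20,
                             ers_mean_change = 15) {
  tibble::tibble(
    ic = as.integer(ic), x = x, y = y, z = z, rv = 0.05,
    hemisphere = ifelse(abs(x) < 5, "midline", ifelse(x < 0, "left", "right")),
    peak_present = peak_present,
    relative_power = ifelse(peak_present, relative_power, -Inf),
    center_frequency = ifelse(peak_present, center_frequency, NA_real_),
    frequency_width = 3,
    erd_area = as.integer(erd_area), ers_area = as.integer(ers_area),
    erd_latency = 0.5, ers_latency = 0.8,
    erd_mean_change = erd_mean_change, ers_mean_change = ers_mean_change,
    scalar_percent = -30)
}
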