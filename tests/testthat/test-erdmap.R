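test_that("Morlet power localizes a tone burst and is flat for a steady tone", {
  fs <- 160
  tt <- seq(-1, 4 - 1 / fs, 1 / fs)
  x <- matrix(0, 1, 800)
  idx <- tt >= 1 & tt < 2
  x[1, idx] <- sin(2 * pi * 12 * tt[idx])
  tf <- morlet_tf(x, fs)
  ridge <- tf$power[1, tf$freqs == 12, ]
  inside <- tf$times >= 1 & tf$times < 2
  expect_gt(sum(ridge[inside], na.rm = TRUE) / sum(ridge, na.rm = TRUE), 0.8)

  xc <- matrix(sin(2 * pi * 10 * tt), 1)
  tfc <- morlet_tf(xc, fs)
  p <- tfc$power[1, tfc$freqs == 10, tfc$valid[tfc$freqs == 10, ]]
  expect_lt(stats::sd(p) / mean(p), 0.05)
  expect_equal(max(morlet_tf(matrix(0, 1, 800), fs)$power, na.rm = TRUE), 0)
  expect_error(morlet_tf(x, fs, freqs = c(10, 90)), "frequencies")
})

test_that("percent change obeys the baseline-ratio identities", {
  fs <- 160
  tt <- seq(-1, 4 - 1 / fs, 1 / fs)
  x <- matrix(sin(2 * pi * 11 * tt), 1)
  e0 <- erd_percent(morlet_tf(x, fs))
  expect_lt(abs(e0$scalar_percent), 0.01)                 # P == R -> 0
  xh <- matrix(sin(2 * pi * 11 * tt) * sqrt(ifelse(tt >= 0, 0.5, 1)), 1)
  eh <- erd_percent(morlet_tf(xh, fs))
  expect_lt(abs(eh$scalar_percent - (-50)), 2)            # half power -> -50
  # scale invariance of the whole percent map
  e2 <- erd_percent(morlet_tf(5 * xh, fs))
  expect_equal(eh$percent, e2$percent, tolerance = 1e-8)
})

test_that("pseudo-T significance detects planted desynchronization, not stationary noise", {
  set.seed(31)
  X <- make_envelope_trials(function(t) ifelse(t >= 0, 0.5, 1),
                            noise_sd = 0.2)
  tf <- morlet_tf(X, 160)
  sg <- pseudo_t_significance(tf)
  ep <- erd_percent(tf)
  regs <- connected_regions(sg, ep$percent)
  big <- largest_region(regs, "ERD")
  expect_gt(big$area, 100)
  # the largest ERD region overlaps the planted ridge (11 Hz, task period)
  expect_lt(big$latency_s, 1)
  # stationary data: nothing significant
  Xn <- make_envelope_trials(function(t) rep(1, length(t)), noise_sd = 0.2)
  sgn <- pseudo_t_significance(morlet_tf(Xn, 160))
  expect_equal(sum(sgn$sig_mask), 0)
  # determinism under the resampling seed
  sg2 <- pseudo_t_significance(tf)
  expect_identical(sg$sig_mask, sg2$sig_mask)
})

test_that("region labeling matches a recursive flood-fill oracle on random masks", {
  set.seed(32)
  for (i in 1:50) {
    mask <- matrix(runif(20 * 50) < 0.35, 20)
    mine <- canonical_labels(erdica:::.label_4connected(mask))
    oracle <- canonical_labels(floodfill_label_oracle(mask))
    expect_identical(mine, oracle)
  }
})

test_that("regions are 4-connected with correct areas, signs, and latencies", {
  mask <- matrix(FALSE, 23, 40)
  mask[3:4, 5:7] <- TRUE          # blob of 6
  mask[10, 20:22] <- TRUE         # blob of 3
  pm <- matrix(0, 23, 40)
  pm[3:4, 5:7] <- -30
  pm[10, 20:22] <- 25
  sig <- list(sig_mask = mask, times = seq(-1 + 0.0125, by = 0.025,
                                           length.out = 40))
  regs <- connected_regions(sig, pm)
  expect_equal(sort(regs$area), c(3L, 6L))
  expect_setequal(regs$sign, c("ERD", "ERS"))
  expect_equal(sum(regs$area), sum(mask))
  erd <- largest_region(regs, "ERD")
  expect_equal(erd$area, 6L)
  expect_equal(erd$latency_s, sig$times[5])
  # single negative resel
  m1 <- matrix(FALSE, 23, 40); m1[10, 25] <- TRUE
  p1 <- matrix(0, 23, 40); p1[10, 25] <- -5
  r1 <- connected_regions(list(sig_mask = m1, times = sig$times), p1)
  expect_equal(r1$area, 1L)
  expect_equal(r1$sign, "ERD")
  expect_equal(r1$latency_s, sig$times[25])
  # diagonal neighbors are NOT merged
  m2 <- matrix(FALSE, 5, 5); m2[2, 2] <- TRUE; m2[3, 3] <- TRUE
  r2 <- connected_regions(list(sig_mask = m2, times = 1:5), m2 * -1)
  expect_equal(nrow(r2), 2)
  # empty mask
  r0 <- connected_regions(list(sig_mask = matrix(FALSE, 3, 3), times = 1:3),
                          matrix(0, 3, 3))
  expect_equal(nrow(r0), 0)
})
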