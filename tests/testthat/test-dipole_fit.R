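test_that("multipole series matches the exact free-space dipole potential", {
  hm <- shared_head_model()
  hm1 <- hm
  hm1$gains <- rep(1, hm1$n_degrees)       # free-space radial transfer
  hm1$cond <- rep(0.33, 4)
  pos <- c(-45, -25, 40); mom <- c(2, -1, 3)
  v_series <- forward_dipole(hm1, pos, mom)
  v_exact <- erdica:::.freespace_potential(pos, mom, hm$electrodes, 0.33)
  v_exact <- v_exact - mean(v_exact)
  expect_lt(max(abs(v_series - v_exact)) / max(abs(v_exact)), 1e-6)
})

test_that("equal-conductivity shells reduce to the homogeneous-sphere solution", {
  hmh <- head_model(conductivities = rep(0.33, 4), n_degrees = 40,
                    grid_spacing_mm = 30)
  n <- seq_len(40)
  expect_equal(hmh$gains, (2 * n + 1) / n, tolerance = 1e-12)
})

test_that("fit recovers off-grid planted dipoles within 2 mm and tiny residual variance", {
  hm <- shared_head_model()
  set.seed(3)
  for (i in 1:6) {
    p <- as.numeric(hm$source_space[sample(nrow(hm$source_space), 1),
                                    c("x", "y", "z")]) + runif(3, -5, 5)
    if (sqrt(sum(p^2)) > 0.85 * hm$radii[1]) p <- 0.8 * p
    f <- fit_dipole(forward_dipole(hm, p, rnorm(3)), hm)
    expect_lt(sqrt(sum((f$position - p)^2)), 2)
    expect_lt(f$residual_variance, 0.01)
  }
})

test_that("residual variance behaves under scaling, sign flip, and two-source maps", {
  hm <- shared_head_model()
  topo <- forward_dipole(hm, c(-40, -20, 45), c(1, 2, 0))
  f1 <- fit_dipole(topo, hm)
  f2 <- fit_dipole(7 * topo, hm)
  f3 <- fit_dipole(-topo, hm)
  expect_equal(f1$residual_variance, f2$residual_variance, tolerance = 1e-10)
  expect_equal(f1$position, f3$position)
  expect_equal(f1$moment, -f3$moment, tolerance = 1e-8)
  two <- forward_dipole(hm, c(-50, -30, 25), c(0, 1, 1)) +
    forward_dipole(hm, c(45, 35, 35), c(1, 0, 1))
  expect_gt(fit_dipole(two, hm)$residual_variance, 0.1)
  expect_error(fit_dipole(rep(0, 30), hm), "degenerate")
})

test_that("refined fit is at least as good as the exhaustive grid", {
  hm <- shared_head_model()
  set.seed(12)
  grid <- as.matrix(hm$source_space[, c("x", "y", "z")])
  for (i in 1:3) {
    topo <- forward_dipole(hm, c(-35, -20, 40) + runif(3, -8, 8), rnorm(3)) +
      0.05 * rnorm(30)
    f <- fit_dipole(topo, hm)
    t0 <- topo - mean(topo)
    grid_rvs <- vapply(seq_len(nrow(grid)), function(j) {
      Lf <- leadfield(hm, grid[j, ])
      m <- qr.coef(qr(Lf), t0)
      1 - sum((Lf %*% m)^2) / sum(t0^2)
    }, numeric(1))
    expect_lte(f$residual_variance, min(grid_rvs) + 1e-3)
  }
})

test_that("residual-variance screen uses the 15% boundary inclusively", {
  keep <- function(rv) screen_rv(structure(list(residual_variance = rv),
                                           class = "dipole_fit"))
  expect_true(keep(0.10))
  expect_true(keep(0.15))
  expect_false(keep(0.151))
})

test_that("region membership respects boxes, hemispheres, and midline regions", {
  atlas <- default_motor_atlas()
  # mean sensorimotor coordinate used in the field falls in the left boxes
  expect_true(in_region(c(-35, -28, 45), atlas, "left"))
  expect_false(in_region(c(-35, -28, 45), atlas, "right"))
  expect_false(in_region(c(0, 60, 0), atlas, "left"))    # frontal pole
  expect_false(in_region(c(0, 60, 0), atlas, "right"))
  # medial SMA matches either hemisphere
  expect_true(in_region(c(5, 0, 60), atlas, "left"))
  expect_true(in_region(c(5, 0, 60), atlas, "right"))
  expect_error(in_region(c(0, 0, 0), atlas[0, ], "left"), "empty")
})

test_that("the shipped atlas file parses and matches the built-in table", {
  path <- system.file("extdata", "motor_atlas.csv", package = "erdica")
  expect_true(nzchar(path))
  a <- read_atlas(path)
  expect_equal(as.data.frame(a), as.data.frame(default_motor_atlas()),
               tolerance = 1e-9)
})
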