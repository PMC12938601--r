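test_that("regression recovers an exact linear relationship", {
  f <- make_feature_cohort(40, noise = 0)
  r <- fit_regression(f)
  g <- glance(r)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  td <- tidy(r)
  expect_equal(td$estimate[td$term == "erd_pct_lh"], -0.3, tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "rel_ers_power_rh"], 0.25,
               tolerance = 1e-8)
  expect_equal(nrow(td), 9)
  expect_lte(g$adj_r_squared, g$r_squared)
  # perfect fit -> zero CV errors
  cv <- cross_validate(f, k = 10, seed = 2)
  expect_lt(cv$mae, 1e-8)
  expect_lt(cv$rmse, 1e-8)
})

test_that("regression guards its preconditions", {
  f <- make_feature_cohort(9)
  expect_error(fit_regression(f), "n > 9")
  f2 <- make_feature_cohort(30)
  f2$ers_pct_lh <- 2 * f2$erd_pct_lh          # collinear
  expect_error(fit_regression(f2), "collinear")
  expect_error(cross_validate(make_feature_cohort(8), k = 10), "exceeds")
})

test_that("cross-validation is deterministic and satisfies rmse >= mae", {
  f <- make_feature_cohort(40, noise = 0.5)
  cv1 <- cross_validate(f, k = 10, seed = 7)
  cv2 <- cross_validate(f, k = 10, seed = 7)
  expect_identical(cv1, cv2)
  expect_gte(cv1$rmse, cv1$mae)
})

test_that("null regression rejects at about the nominal 5% rate", {
  set.seed(99)
  n <- 109
  rejections <- vapply(1:200, function(r) {
    f <- make_feature_cohort(n, seed = 1000 + r)
    f$classdis <- sample(f$classdis)          # break the association
    glance(fit_regression(f))$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("per-hand clustering separates planted blobs and maps labels by ClassDis", {
  set.seed(51)
  n <- 30
  good <- tibble::tibble(erd_pct_lh = rnorm(n, -40, 3),
                         rel_ers_power_lh = rnorm(n, 1, 0.1),
                         classdis = rnorm(n, 1.3, 0.1))
  poor <- tibble::tibble(erd_pct_lh = rnorm(n, -5, 3),
                         rel_ers_power_lh = rnorm(n, 0.2, 0.1),
                         classdis = rnorm(n, 0.7, 0.1))
  f <- dplyr::bind_rows(good, poor)
  lab <- cluster_one_hand(f, "left", seed = 1)
  expect_identical(lab, rep(c("good", "poor"), each = n))
  # negating ClassDis flips which cluster is called good
  f2 <- f; f2$classdis <- -f2$classdis
  lab2 <- cluster_one_hand(f2, "left", seed = 1)
  expect_identical(lab2, rep(c("poor", "good"), each = n))
  # column order is irrelevant
  f3 <- f[, c(3, 1, 2)]
  expect_identical(cluster_one_hand(f3, "left", seed = 1), lab)
  # degenerate identical features warn and collapse
  f4 <- f; f4$erd_pct_lh <- 0; f4$rel_ers_power_lh <- 0; f4$classdis <- 1
  expect_warning(lab4 <- cluster_one_hand(f4, "left"), "degenerate")
  expect_equal(length(unique(lab4)), 1)
})

test_that("group assignment implements the four-way mapping", {
  g <- assign_groups(c("good", "good", "poor", "poor"),
                     c("good", "poor", "good", "poor"))
  expect_identical(g$group, c("good", "LgoodRpoor", "LpoorRgood", "poor"))
})

test_that("Tukey-Kramer agrees with a hand-worked two-group fixture and TukeyHSD", {
  # fixture: groups {1,2,3,4,5} and {3,4,5,6,9}
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 9)
  # hand computation: means 3 and 5.4, pooled MSE = (10 + 21.2) / 8 = 3.9
  # SE = sqrt(3.9/2 * (1/5 + 1/5)) = sqrt(0.78), q = 2.4 / 0.8832 = 2.7175
  tk <- tukey_kramer(c(a, b), rep(c("A", "B"), each = 5))
  expect_equal(tk$q, 2.4 / sqrt(0.78), tolerance = 1e-10)
  expect_equal(tk$p_value,
               stats::ptukey(2.4 / sqrt(0.78), 2, 8, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against stats::TukeyHSD on unequal-n three-group data
  set.seed(52)
  v <- c(rnorm(7, 0), rnorm(5, 1), rnorm(9, 2))
  g <- rep(c("a", "b", "c"), c(7, 5, 9))
  mine <- tukey_kramer(v, g)
  ref <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
  expect_equal(sort(mine$p_value), sort(unname(ref[, "p adj"])),
               tolerance = 1e-8)
})

test_that("Games-Howell reduces to a Welch-style comparison for two groups", {
  set.seed(53)
  a <- rnorm(12, 0, 1); b <- rnorm(20, 1.5, 3)
  gh <- games_howell(c(a, b), rep(c("A", "B"), c(12, 20)))
  w <- stats::t.test(a, b)
  expect_equal(gh$q, abs(unname(w$statistic)) * sqrt(2), tolerance = 1e-10)
  expect_equal(gh$df, unname(w$parameter), tolerance = 1e-10)
  expect_equal(gh$p_value, w$p.value, tolerance = 1e-6)
})

test_that("group statistics switch tests on Levene and run paired contrasts", {
  set.seed(54)
  n <- 15
  f <- dplyr::bind_rows(
    tibble::tibble(group = "good", erd_pct_lh = rnorm(n, -40, 4),
                   erd_pct_rh = rnorm(n, -40, 4),
                   rel_ers_power_lh = rnorm(n, 1, 0.1),
                   rel_ers_power_rh = rnorm(n, 1, 0.1)),
    tibble::tibble(group = "poor", erd_pct_lh = rnorm(n, -5, 4),
                   erd_pct_rh = rnorm(n, -5, 4),
                   rel_ers_power_lh = rnorm(n, 0.2, 0.8),  # variance violation
                   rel_ers_power_rh = rnorm(n, 0.2, 0.1)))
  gs <- group_statistics(f)
  expect_equal(nrow(gs$omnibus), 4)
  expect_true(all(gs$omnibus$p_value[gs$omnibus$feature
                                     %in% c("erd_pct_lh", "erd_pct_rh")] < 0.01))
  # the heteroscedastic feature routes to Welch + Games-Howell
  expect_equal(gs$omnibus$test[gs$omnibus$feature == "rel_ers_power_lh"],
               "welch")
  expect_equal(unique(gs$posthoc$method[gs$posthoc$feature ==
                                          "rel_ers_power_lh"]),
               "games-howell")
  expect_equal(nrow(gs$paired), 4)     # 2 groups x 2 metrics
  # paired t on identical LH/RH values: NA statistic (zero variance)
  f2 <- f
  f2$erd_pct_rh <- f2$erd_pct_lh
  gs2 <- group_statistics(f2)
  expect_true(all(is.na(
    gs2$paired$statistic[gs2$paired$metric == "erd_pct"])))
  # tiny groups are excluded with a warning
  f3 <- dplyr::bind_rows(f, tibble::tibble(
    group = "LpoorRgood", erd_pct_lh = -20, erd_pct_rh = -20,
    rel_ers_power_lh = 0.5, rel_ers_power_rh = 0.5))
  expect_warning(group_statistics(f3), "n < 2")
})

test_that("feature extraction flags missing peaks and validates selections", {
  sel <- dplyr::bind_rows(
    make_profile_row(1, x = 40) |>
      dplyr::mutate(role = "contra-ERD", task_side = "left",
                    scalar_percent = -35),
    make_profile_row(2, x = -40) |>
      dplyr::mutate(role = "ipsi-ERS", task_side = "left",
                    scalar_percent = 12, peak_present = FALSE,
                    relative_power = -Inf),
    make_profile_row(3, x = -40) |>
      dplyr::mutate(role = "contra-ERD", task_side = "right",
                    scalar_percent = -28),
    make_profile_row(4, x = 40) |>
      dplyr::mutate(role = "ipsi-ERS", task_side = "right",
                    scalar_percent = 9))
  f <- extract_features(sel, classdis = 1.1, subject_id = "S9")
  expect_equal(f$erd_pct_lh, -35)
  expect_equal(f$ers_pct_lh, 12)
  expect_equal(f$rel_ers_power_lh, 0)          # missing peak -> 0, flagged
  expect_match(f$missing_peak_flags, "ipsi-ERS/left")
  expect_equal(f$rel_ers_power_rh, 0.5)
  expect_equal(ncol(f |> dplyr::select(dplyr::starts_with("erd"),
                                       dplyr::starts_with("ers"),
                                       dplyr::starts_with("rel"))), 8)
  expect_error(extract_features(sel[-1, ], 1, "S9"),
               class = "erdica_no_candidate")
})
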