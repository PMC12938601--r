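# Hand-built candidate fixtures for the selection rules. Positions
# (+/-40, -25, 50) sit inside the sensorimotor atlas boxes.

test_that("contralateral ERD selection follows area, then the power fallback", {
  # left-hand imagery -> contralateral = right hemisphere (x > 0)
  cand <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.7, erd_area = 40),
    make_profile_row(2, x = 42, relative_power = 0.6, erd_area = 10),
    make_profile_row(3, x = 44, relative_power = 0.5, erd_area = 0))
  s <- select_contralateral_erd(cand, "left")
  expect_equal(s$ic, 1L)
  expect_equal(s$provenance, "rule3-area")
  # areas {40,10,0} -> the 40 wins even if its power is lowest of the three
  cand2 <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.7, erd_area = 0),
    make_profile_row(2, x = 42, relative_power = 0.5, erd_area = 10),
    make_profile_row(3, x = 44, relative_power = 0.2, erd_area = 40))
  expect_equal(select_contralateral_erd(cand2, "left")$ic, 3L)
  # all areas zero -> highest relative power, fallback provenance
  cand3 <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.7, erd_area = 0),
    make_profile_row(2, x = 42, relative_power = 0.5, erd_area = 0),
    make_profile_row(3, x = 44, relative_power = 0.2, erd_area = 0))
  s3 <- select_contralateral_erd(cand3, "left")
  expect_equal(s3$ic, 1L)
  expect_equal(s3$provenance, "rule3-fallback-power")
})

test_that("the top-3 power gate (Rule 2) restricts which areas Rule 3 may consider", {
  cand <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.9, erd_area = 0),
    make_profile_row(2, x = 41, relative_power = 0.8, erd_area = 0),
    make_profile_row(3, x = 42, relative_power = 0.7, erd_area = 50),
    make_profile_row(4, x = 43, relative_power = 0.6, erd_area = 90),
    make_profile_row(5, x = 44, relative_power = 0.5, erd_area = 99))
  s <- select_contralateral_erd(cand, "left")
  expect_equal(s$ic, 3L)        # 90 and 99 are outside the top-3 powers
  expect_equal(s$provenance, "rule3-area")
})

test_that("ipsilateral ERS selection gates on the mu/beta peak and uses ERS areas", {
  # left-hand imagery -> ipsilateral = left hemisphere (x < 0)
  cand <- dplyr::bind_rows(
    make_profile_row(1, x = -40, relative_power = 0.5, ers_area = 0),
    make_profile_row(2, x = -42, relative_power = 0.4, ers_area = 12))
  s <- select_ipsilateral_ers(cand, "left")
  expect_equal(s$ic, 2L)
  expect_equal(s$provenance, "rule3-area")
  # all zero ERS area -> power fallback
  cand2 <- dplyr::bind_rows(
    make_profile_row(1, x = -40, relative_power = 0.4, ers_area = 0),
    make_profile_row(2, x = -42, relative_power = 0.6, ers_area = 0))
  s2 <- select_ipsilateral_ers(cand2, "left")
  expect_equal(s2$ic, 2L)
  expect_equal(s2$provenance, "rule3-fallback-power")
  # a candidate without any in-band peak is excluded even with a large area
  cand3 <- dplyr::bind_rows(
    make_profile_row(1, x = -40, relative_power = 0.3, ers_area = 4),
    make_profile_row(2, x = -42, peak_present = FALSE, ers_area = 80))
  expect_equal(select_ipsilateral_ers(cand3, "left")$ic, 1L)
  # peak gate empties the set: error by default, relaxed when configured
  cand4 <- make_profile_row(2, x = -42, peak_present = FALSE, ers_area = 80)
  expect_error(select_ipsilateral_ers(cand4, "left"),
               class = "erdica_no_candidate")
  s4 <- select_ipsilateral_ers(cand4, "left", relax_rule2 = TRUE)
  expect_equal(s4$provenance, "rule2-relaxed")
})

test_that("Rule 1 region/hemisphere filtering is decisive", {
  # only left-hemisphere candidates: contralateral selection for a
  # right-hand task works, for a left-hand task it fails
  cand <- dplyr::bind_rows(
    make_profile_row(1, x = -40, relative_power = 0.5, erd_area = 10),
    make_profile_row(2, x = -42, relative_power = 0.4, erd_area = 0))
  expect_equal(select_contralateral_erd(cand, "right")$ic, 1L)
  expect_error(select_contralateral_erd(cand, "left"),
               class = "erdica_no_candidate")
  # positions outside every atlas box fail Rule 1 regardless of hemisphere
  frontal <- make_profile_row(1, x = 40, y = 70, z = 0, erd_area = 50)
  expect_error(select_contralateral_erd(frontal, "left"),
               class = "erdica_no_candidate")
})

test_that("select_all yields four picks with correct hemisphere lateralization", {
  # one class decomposition per task, each with candidates in both
  # hemispheres
  profs <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.6, erd_area = 30),
    make_profile_row(2, x = -40, relative_power = 0.8, ers_area = 10),
    make_profile_row(3, x = -42, relative_power = 0.3, erd_area = 20),
    make_profile_row(4, x = 42, relative_power = 0.5, ers_area = 5))
  sel <- select_all(profs, profs)
  expect_equal(nrow(sel), 4)
  expect_setequal(paste(sel$role, sel$task_side),
                  c("contra-ERD left", "ipsi-ERS left",
                    "contra-ERD right", "ipsi-ERS right"))
  # contralateral pick sits opposite the imagined hand, ipsilateral with it
  get <- function(role, side) sel$x[sel$role == role & sel$task_side == side]
  expect_gt(get("contra-ERD", "left"), 0)
  expect_lt(get("contra-ERD", "right"), 0)
  expect_lt(get("ipsi-ERS", "left"), 0)
  expect_gt(get("ipsi-ERS", "right"), 0)
  # a one-hemisphere candidate set fails for the task needing the other
  left_only <- dplyr::bind_rows(
    make_profile_row(1, x = -40, erd_area = 10),
    make_profile_row(2, x = -42, ers_area = 5))
  expect_error(select_all(left_only, left_only),
               class = "erdica_no_candidate")
})

test_that("selection is invariant to candidate order and ties break deterministically", {
  cand <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.7, erd_area = 40),
    make_profile_row(2, x = 42, relative_power = 0.6, erd_area = 10),
    make_profile_row(3, x = 44, relative_power = 0.5, erd_area = 0),
    make_profile_row(4, x = 46, relative_power = 0.45, erd_area = 99))
  base <- select_contralateral_erd(cand, "left")
  for (i in 1:5) {
    perm <- cand[sample(nrow(cand)), ]
    s <- select_contralateral_erd(perm, "left")
    expect_equal(s$ic, base$ic)
    expect_equal(s$provenance, base$provenance)
  }
  # equal power tie -> lower center frequency enters the top-3
  tie <- dplyr::bind_rows(
    make_profile_row(1, x = 40, relative_power = 0.5,
                     center_frequency = 22, erd_area = 0),
    make_profile_row(2, x = 42, relative_power = 0.5,
                     center_frequency = 10, erd_area = 0),
    make_profile_row(3, x = 44, relative_power = 0.5,
                     center_frequency = 16, erd_area = 0),
    make_profile_row(4, x = 46, relative_power = 0.5,
                     center_frequency = 28, erd_area = 70))
  s <- select_contralateral_erd(tie, "left")
  expect_equal(s$ic, 2L)        # fallback power tie -> lower frequency
  # equal area tie -> larger absolute mean change
  tie2 <- dplyr::bind_rows(
    make_profile_row(1, x = 40, erd_area = 30, erd_mean_change = -10),
    make_profile_row(2, x = 42, erd_area = 30, erd_mean_change = -35),
    make_profile_row(3, x = 44, erd_area = 5))
  expect_equal(select_contralateral_erd(tie2, "left")$ic, 2L)
  # provenance vocabulary is closed
  expect_true(base$provenance %in%
                c("rule3-area", "rule3-fallback-power", "rule2-relaxed"))
})
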