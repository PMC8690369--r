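ep_days <- function(eps) {
  data.frame(patient_id = eps$patient_id,
             start = as.numeric(eps$start - D0),
             end = as.numeric(eps$end - D0))
}

test_that("primary proxy start, end and merge rules on canonical stay patterns", {
  ## 7-night stay: start at admission, end 7 quiet days after discharge
  e <- identify_primary_episodes(mk_stays("A", 0, 7))
  expect_identical(ep_days(e), data.frame(patient_id = "A", start = 0, end = 14))

  ## 3-night stay never qualifies
  expect_identical(nrow(identify_primary_episodes(mk_stays("A", 0, 3))), 0L)

  ## readmission 4 days after discharge merges; end = last discharge + 7
  e <- identify_primary_episodes(mk_stays("A", c(0, 14), c(10, 16)))
  expect_identical(ep_days(e), data.frame(patient_id = "A", start = 0, end = 23))

  ## 30-day variant keeps chaining across a 24-day gap
  e <- identify_primary_episodes(mk_stays("A", c(0, 14, 40), c(10, 16, 45)),
                                 merge_gap_days = 30)
  expect_identical(ep_days(e), data.frame(patient_id = "A", start = 0, end = 75))

  ## overlapping stays (ward transfer) union before clustering
  e <- identify_primary_episodes(mk_stays("A", c(0, 3), c(5, 9)))
  expect_identical(ep_days(e), data.frame(patient_id = "A", start = 0, end = 16))
})

test_that("cluster duration rule: total covered days or any single stay", {
  ## two 4-night stays 3 days apart: 8 covered days in one cluster
  stays <- mk_stays("A", c(0, 7), c(4, 11))
  expect_identical(nrow(identify_primary_episodes(stays)), 1L)
  expect_identical(nrow(identify_primary_episodes(stays, duration_rule = "single_stay")),
                   0L)
})

test_that("treatment lines split on substance changes only", {
  ## same substance refills: one line
  l <- build_treatment_lines(mk_disp("A", c(0, 30, 60), "N05AH03"))
  expect_identical(nrow(l), 1L)
  expect_identical(as.numeric(l$line_start - D0), 0)

  ## substance change starts a new line at its first dispensation
  l <- build_treatment_lines(dplyr::bind_rows(mk_disp("A", 0, "N05AH03"),
                                              mk_disp("A", 40, "N05AX08")))
  expect_identical(nrow(l), 2L)
  expect_identical(as.numeric(l$line_start[2] - D0), 40)

  ## empty stream, and non-antipsychotic codes are ignored
  expect_identical(nrow(build_treatment_lines(mk_disp("A", numeric(), character()))), 0L)
  expect_identical(nrow(build_treatment_lines(mk_disp("A", c(0, 30), "C07AB02"))), 0L)
})

test_that("switch proxy requires a new line within 30 days of discharge", {
  stay <- mk_stays("A", 98, 100, code = "F31.1")
  lines10 <- build_treatment_lines(dplyr::bind_rows(
    mk_disp("A", -50, "N05AH03"), mk_disp("A", 110, "N05AX08")))
  e <- identify_switch_episodes(stay, lines10)
  expect_identical(ep_days(e), data.frame(patient_id = "A", start = 98, end = 107))

  ## new line 40 days after discharge: outside the window
  lines40 <- build_treatment_lines(dplyr::bind_rows(
    mk_disp("A", -50, "N05AH03"), mk_disp("A", 140, "N05AX08")))
  expect_identical(nrow(identify_switch_episodes(stay, lines40)), 0L)

  ## same-substance refill in the window is not a switch
  refill <- build_treatment_lines(dplyr::bind_rows(
    mk_disp("A", -50, "N05AH03"), mk_disp("A", 110, "N05AH03")))
  expect_identical(nrow(identify_switch_episodes(stay, refill)), 0L)

  ## a same-day stay (no overnight) never qualifies
  e <- identify_switch_episodes(mk_stays("A", 100, 100, code = "F31.1"), lines10)
  expect_identical(nrow(e), 0L)
})

test_that("high-frequency proxy window opening and quiet-period closure", {
  ## 8 visits in the first fortnight: start at the window end, quiet closure
  e <- identify_highfreq_episodes(mk_visits("A", 0:7))
  expect_identical(ep_days(e), data.frame(patient_id = "A", start = 13, end = 14))

  ## 7 visits in any fortnight: below threshold
  expect_identical(nrow(identify_highfreq_episodes(mk_visits("A", seq(0, 12, 2)))), 0L)

  ## persistent visits (about 2/week) keep the episode open until the stream
  ## and follow-up end
  v <- mk_visits("A", c(0:7, seq(14, 200, by = 3)))
  e <- identify_highfreq_episodes(v, follow_up_end = D0 + 200)
  expect_identical(nrow(e), 1L)
  expect_identical(as.numeric(e$start - D0), 13)
  expect_gte(as.numeric(e$end - D0), 194) # only the unobserved tail quiets it
})

test_that("episode streams are order-invariant and idempotent", {
  withr::local_seed(77)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    stays <- mk_stays("A", adm <- sort(sample(0:300, n)),
                      adm + sample(0:15, n, replace = TRUE))
    shuf <- stays[sample(n), ]
    for (gap in c(7, 30)) {
      a <- identify_primary_episodes(stays, merge_gap_days = gap)
      b <- identify_primary_episodes(shuf, merge_gap_days = gap)
      expect_identical(a, b)
      expect_identical(identify_primary_episodes(stays, merge_gap_days = gap), a)
    }
  }
})

test_that("episodes are disjoint and separated by more than the merge gap", {
  withr::local_seed(78)
  for (i in 1:30) {
    n <- sample(1:20, 1)
    stays <- mk_stays("A", adm <- sort(sample(0:1000, n)),
                      adm + sample(0:20, n, replace = TRUE))
    for (gap in c(7, 30)) {
      e <- identify_primary_episodes(stays, merge_gap_days = gap)
      if (nrow(e) > 1) {
        expect_true(all(diff(as.numeric(e$start)) > 0))
        ## next admission exceeds previous episode end (= discharge + gap)
        expect_true(all(as.numeric(e$start[-1]) > as.numeric(e$end[-nrow(e)])))
      }
      expect_identical(e$ordinal, seq_len(nrow(e)))
    }
  }
})

test_that("widening the merge window never adds episodes under the single-stay rule", {
  withr::local_seed(80)
  for (i in 1:40) {
    n <- sample(1:20, 1)
    adm <- sort(sample(0:1000, n))
    stays <- mk_stays("A", adm, adm + sample(0:20, n, replace = TRUE))
    n7 <- nrow(identify_primary_episodes(stays, duration_rule = "single_stay",
                                         merge_gap_days = 7))
    n30 <- nrow(identify_primary_episodes(stays, duration_rule = "single_stay",
                                          merge_gap_days = 30))
    expect_lte(n30, n7)
  }
})

test_that("interval implementation matches the brute-force day scanner", {
  withr::local_seed(79)
  for (i in 1:150) {
    n <- sample(1:20, 1)
    adm <- sort(sample(0:1000, n))
    dur <- sample(0:20, n, replace = TRUE)
    gap <- sample(c(7, 30), 1)
    rule <- sample(c("total_or_single", "single_stay"), 1)
    got <- identify_primary_episodes(mk_stays("A", adm, adm + dur),
                                     merge_gap_days = gap, duration_rule = rule)
    want <- primary_episodes_oracle(adm, adm + dur, merge_gap_days = gap,
                                    duration_rule = rule)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(as.numeric(got$start - D0), as.numeric(want$start))
      expect_equal(as.numeric(got$end - D0), as.numeric(want$end))
    }
  }
})

test_that("the hand-built fixture yields exactly the hand-listed episodes", {
  b <- fixture_bundle()
  for (proxy in c("primary", "primary30", "switch", "highfreq")) {
    got <- ep_days(identify_episodes(b, proxy))
    want <- fixture_expected(proxy)
    expect_identical(got, want, info = proxy)
  }
})
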