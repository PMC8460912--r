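# The rate pairs behind the headline test-vs-control sentences (rates in
# mmol L-1 d-1, printed integer percent figures after rounding).
printed_contrasts <- data.frame(
  what = c("ch4 down under O2", "acetate consumption down", "ch4 rebound up",
           "caproate still down", "ch4 at double-rate leak",
           "caproate at double-rate leak", "butyrate down (BCR)",
           "ch4 down (BCR)", "ch4 partial recovery (BCR)"),
  test = c(6.05, 1.80, 19.5, 1.78, 5.33, 1.06, 1.22, 1.41, 11.9),
  control = c(16.5, 2.91, 16.5, 2.12, 16.5, 2.12, 2.25, 15.9, 15.9),
  kind = c("change", "change", "change", "change", "of_control",
           "of_control", "change", "change", "change"),
  printed = c(63, 38, 18, 16, 32, 50, 46, 91, 25))

test_that("all nine printed percent figures are reproduced after rounding", {
  for (i in seq_len(nrow(printed_contrasts))) {
    row <- printed_contrasts[i, ]
    got <- if (row$kind == "change") {
      abs(round_half_out(percent_change(row$test, row$control)))
    } else {
      round_half_out(rate_as_pct_of_control(row$test, row$control))
    }
    expect_identical(unname(got), row$printed)
  }
})

test_that("percent identities hold exactly before rounding", {
  for (i in seq_len(nrow(printed_contrasts))) {
    tst <- printed_contrasts$test[i]; ctl <- printed_contrasts$control[i]
    expect_equal(percent_change(tst, ctl), 100 * (tst - ctl) / ctl)
    if (tst < ctl)
      expect_equal(rate_as_pct_of_control(tst, ctl) +
                     abs(percent_change(tst, ctl)), 100)
  }
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_error(percent_change(1, 0), "control rate is zero")
  expect_error(rate_as_pct_of_control(1, -2), "undefined")
})

test_that("report rounding is half-away-from-zero and report-layer only", {
  expect_identical(round_half_out(45.8), 46)
  expect_identical(round_half_out(91.13), 91)
  expect_identical(round_half_out(-63.33), -63)
  expect_identical(round_half_out(0.5), 1)
  expect_identical(round_half_out(-0.5), -1)
  expect_identical(round_half_out(4.142857, 1), 4.1)
})

test_that("fold changes divide, with the 6.4x and 4.1x cases as printed", {
  expect_equal(fold_change(2.4, 2.4), 1)
  expect_equal(round_half_out(fold_change(0.76, 0.119), 1), 6.4)
  expect_equal(round_half_out(fold_change(0.29, 0.07), 1), 4.1)
  expect_error(fold_change(1, 0), "undefined")
  # brute-force toy oracle over all pairs
  vals <- c(0.3, 1.7, 2.5)
  for (a in vals) for (b in vals) expect_equal(fold_change(a, b), a / b)
})

test_that("comparison tables align periods, stay unrounded, and ignore row order", {
  mk <- function(rates) data.frame(
    period = rep(c("P1", "P2"), each = 2),
    compound = rep(c("ch4", "n-caproate"), 2),
    rate = rates)
  tst <- mk(c(6.05, 0.56, 19.5, 1.78))
  ctl <- mk(c(16.5, 2.12, 16.5, 2.12))
  tab <- comparison_table(tst, ctl)
  expect_equal(nrow(tab), 4)
  i <- tab$period == "P1" & tab$compound == "ch4"
  expect_equal(tab$pct_change[i], 100 * (6.05 / 16.5 - 1))   # unrounded
  expect_identical(tab$pct_change_report[i], -63)            # report layer
  # identical tables give all-zero changes
  expect_true(all(comparison_table(ctl, ctl)$pct_change == 0))
  # shuffled input rows produce the identical table
  expect_identical(comparison_table(tst[c(3, 1, 4, 2), ], ctl), tab)
  # unmatched period labels are named in the error
  ctl2 <- ctl; ctl2$period[ctl2$period == "P2"] <- "P3"
  expect_error(comparison_table(tst, ctl2), "P2.*P3|P3.*P2")
})

test_that("the report phrase flags figures that do not recompute", {
  expect_match(contrast_phrase(6.05, 16.5, printed = 63), "^63% less")
  expect_match(contrast_phrase(19.5, 16.5, printed = 18), "^18% higher")
  # the one stated figure that disagrees with its own operands
  expect_match(contrast_phrase(0.56, 2.12, printed = 72),
               "recomputed 74%, stated 72%")
})
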