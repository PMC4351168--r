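test_that("cohen_kappa matches frozen values on audit-shaped tables", {
  k3 <- function(...) round_half_away(cohen_kappa(contingency_table(...)), 3)
  expect_equal(k3(21, 9, 0, 7), 0.469)     # blood pressure, older panel
  expect_equal(k3(20, 19, 0, 0), 0.000)    # fasting glucose, older panel
  expect_equal(k3(214, 152, 0, 49), 0.250) # pooled, older panel
  expect_equal(k3(293, 73, 0, 49), 0.487)  # pooled, newer panel
  expect_equal(k3(25, 25, 25, 25), 0)      # independence
  expect_equal(k3(10, 0, 0, 10), 1)
  expect_equal(k3(0, 10, 10, 0), -1)
  # single-diagonal-cell convention: everyone agrees on every item
  expect_equal(cohen_kappa(contingency_table(39, 0, 0, 0)), 1)
  expect_equal(cohen_kappa(contingency_table(0, 0, 0, 12)), 1)
  expect_error(cohen_kappa(contingency_table(0, 0, 0, 0)),
               class = "chipconcord_config_error")
})

test_that("kappa is symmetric, bounded, and 1 exactly when discordance-free", {
  withr::with_seed(7, {
    for (i in 1:200) {
      cells <- as.integer(rmultinom(1, sample(1:60, 1), runif(4)))
      tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      k <- cohen_kappa(tab)
      expect_gte(k, -1); expect_lte(k, 1)
      # swap the two methods (fn <-> fp)
      expect_equal(cohen_kappa(contingency_table(
        cells[1], cells[3], cells[2], cells[4])), k)
      # relabel present <-> absent (tp <-> tn, fn <-> fp)
      expect_equal(cohen_kappa(contingency_table(
        cells[4], cells[3], cells[2], cells[1])), k)
      # diagonal reflection (tp <-> tn at fixed fn/fp): Pr(e) is symmetric
      # in the diagonal cells, so kappa cannot tell the two apart
      expect_equal(cohen_kappa(contingency_table(
        cells[4], cells[2], cells[3], cells[1])), k)
      expect_equal(k == 1, cells[2] == 0 && cells[3] == 0)
    }
  })
})

test_that("kappa equals the per-item brute-force oracle", {
  withr::with_seed(13, {
    for (i in 1:300) {
      cells <- as.integer(rmultinom(1, sample(1:50, 1), runif(4)))
      expect_equal(
        cohen_kappa(contingency_table(cells[1], cells[2], cells[3], cells[4])),
        kappa_per_item(cells[1], cells[2], cells[3], cells[4]))
    }
  })
})

test_that("false-negative rate supports both denominators", {
  tab <- contingency_table(214, 152, 0, 49)
  expect_equal(round_half_away(false_negative_rate(tab, "reported"), 1), 36.6)
  expect_equal(round_half_away(false_negative_rate(tab, "formula"), 1), 41.5)
  none <- contingency_table(10, 0, 0, 5)
  expect_equal(false_negative_rate(none, "reported"), 0)
  expect_equal(false_negative_rate(none, "formula"), 0)
  off_only <- contingency_table(0, 0, 0, 5)
  expect_error(false_negative_rate(off_only, "formula"),
               class = "chipconcord_config_error")
})

test_that("false-positive rate uses the truly-off-chip denominator", {
  expect_equal(false_positive_rate(contingency_table(214, 152, 0, 49)), 0)
  expect_equal(false_positive_rate(contingency_table(0, 0, 5, 5)), 50)
  expect_equal(false_positive_rate(contingency_table(1, 1, 0, 9)), 0)
  expect_error(false_positive_rate(contingency_table(5, 2, 0, 0)),
               class = "chipconcord_config_error")
})

test_that("Landis-Koch banding follows the tabulated thresholds", {
  expect_equal(landis_band(0.469), "moderate")
  expect_equal(landis_band(0.841), "perfect")
  expect_equal(landis_band(0.250), "fair")
  expect_equal(landis_band(0.166), "slight")
  expect_equal(landis_band(-0.2), "no agreement")
  expect_equal(landis_band(c(0, 0.205, 0.61, 0.80, 0.805, 0.81)),
               c("slight", "fair", "substantial", "substantial",
                 "substantial", "perfect"))
})

test_that("reconstruct_split recovers unpublished cells up to mirror symmetry", {
  # kappa is invariant under tp <-> tn at fixed fn/fp, so a single row can
  # only pin the split up to reflection: the admissible set is the mirror pair
  s1 <- reconstruct_split(37, 28, fn = 9, fp = 0, kappa_printed = 0.469)
  expect_equal(nrow(s1), 2L)
  expect_setequal(s1$tp, c(21L, 7L))
  expect_equal(s1$tn, rev(s1$tp))
  s2 <- reconstruct_split(39, 20, fn = 19, fp = 0, kappa_printed = 0.000)
  expect_setequal(s2$tp, c(20L, 0L))
  # degenerate perfect agreement: every split of an all-concordant table
  s3 <- reconstruct_split(5, 5, fn = 0, fp = 0, kappa_printed = 1.000)
  expect_equal(nrow(s3), 6L)
  expect_error(reconstruct_split(10, 5, fn = 2, fp = 0, kappa_printed = 0.5),
               class = "chipconcord_config_error")  # marginals inconsistent
  expect_error(reconstruct_split(37, 28, fn = 9, fp = 0,
                                 kappa_printed = 0.9),
               class = "chipconcord_validation_error")  # irreconcilable
})

test_that("agreement_summary rounds for reporting and degrades gracefully", {
  s <- agreement_summary(contingency_table(214, 152, 0, 49))
  expect_equal(s$concordance_pct, 63.4)
  expect_equal(s$discordance_pct, 36.6)
  expect_equal(s$kappa, 0.250)
  expect_equal(s$band, "fair")
  expect_equal(s$fnr_reported, 36.6)
  expect_equal(s$fnr_formula, 41.5)
  expect_equal(s$fpr, 0)
  # all-on-chip group: FPR has a zero denominator, reported as NA
  s2 <- agreement_summary(contingency_table(39, 0, 0, 0))
  expect_equal(s2$kappa, 1)
  expect_true(is.na(s2$fpr))
  expect_output(print(s), "kappa = 0.250")
})

test_that("rounding is half-away-from-zero at reporting precision", {
  expect_equal(round_half_away(0.2495, 3), 0.250)
  expect_equal(round_half_away(-0.2495, 3), -0.250)
  expect_equal(round_half_away(75.675, 1), 75.7)
  expect_equal(round_half_away(0.8415, 3), 0.842)
  expect_equal(round_half_away(2.5), 3)
})
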